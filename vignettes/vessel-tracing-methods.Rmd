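---
title: "PSF-aware vessel tracing and in vivo / ex vivo network comparison"
author: "vesseltrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PSF-aware vessel tracing and network comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesseltrace)
```

## The problem

Two-photon fluorescence microscopy resolves the cortical
microvasculature down to capillaries, both in vivo (plasma dye through a
cranial window) and ex vivo (gel-perfused, fructose-cleared brains).
Imaging cleared tissue through a water-immersion objective introduces
spherical aberration: the axial extent of the point spread function
(PSF) grows with imaging depth, and the apparent axial step size is
compressed by the refractive-index ratio of clearing agent to water.
Vessels whose diameter is comparable to the PSF are blurred
anisotropically, and any diameter estimator that ignores the depth
dependence inflates small-vessel diameters more and more with depth.

`vesseltrace` implements a tracing and comparison pipeline that models
these effects explicitly: a depth-varying anisotropic Gaussian PSF
calibrated from bead stacks, a medial-atom centerline tracker whose
boundary model is the vessel cross-section convolved with the marginal
PSF, thin-plate-spline registration of traced trees between in vivo and
ex vivo image spaces, and morphometry for the comparative questions
(classwise shrinkage, perfusion success, shadowing, signal attenuation
with depth).

## The PSF model

The PSF is an axis-aligned 3D Gaussian. The lateral full width at half
maximum (FWHM) is constant with depth; the axial FWHM is linear in
depth below the cortical surface,

$$\mathrm{FWHM}_z(z) = a_0 + a_1 z,$$

with defaults $a_0 = 3.4\,\mu m$ and $a_1 = (7.5-3.4)/1000\,\mu
m/\mu m$: the values measured for fructose-cleared tissue under a
1.05 NA water-immersion objective, where the width rises from
3.4 um at the surface to 7.5 um at 1 mm. In vivo the same model is
used with $a_1 = 0$. Everywhere in the package
$\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$.

Calibration (`fitBeadFwhm`, `calibratePsfDepthModel`) fits 1D Gaussians
to the axial and lateral profiles of sub-resolution beads, after the
same 2D blur used for vascular images, then regresses axial FWHM on
depth by ordinary least squares. The lateral slope is tested against
zero (alpha = 0.05); when it is not significant the lateral FWHM is the
mean of the lateral fits. The reported widths deliberately include the
conditioning blur and the bead size: the tracker operates on identically
conditioned images, so this *effective* PSF is the self-consistent
quantity (the bead and blur inflate the 3.4 um intercept by about 1%).
Bead fits use the profile at voxel centres along the fit axis — the
Gaussian's centre is a free parameter — because interpolating along the
axis widens sub-voxel profiles. Lateral bead widths sit near half a
voxel at 1.5 um sampling and are accordingly the least certain output
of calibration.

The refractive-index correction is a pure metadata operation:
`rescaleAxial` multiplies the apparent axial step by
$n_{agent}/n_{water}$ (1.49/1.33 = 1.12 for fructose under water
immersion, turning an apparent 1.34 um step into a true 1.5 um step).
The subsequent isotropic resampling realizes the correction on the
grid, so the data are interpolated once, not twice.

## Image conditioning

The fixed chain before tracking is: 2D lateral Gaussian blur of FWHM
1.5 um, trilinear resampling to an isotropic 1.5 um grid, then
non-local-means denoising. Convolutions use reflect padding and
discrete kernels whose *discrete* second moment equals the nominal
$\sigma^2$, so chained blurs obey the quadrature rule
$\mathrm{FWHM}_{tot}^2 = \sum_i \mathrm{FWHM}_i^2$ that the calibration
and the tracker assume. Non-local means uses a $3^3$ patch, $7^3$
search window, and a bandwidth tied to a noise estimate from
six-neighbour pseudo-residuals; on noiseless input the estimate
collapses and the filter is essentially the identity. These NLM
parameters are package defaults (the method is standard; its parameters
are not dictated by the measurement model) and are recorded in the
volume's provenance.

## Medial-atom tracking

Vessels are traced as chains of *medial atoms*: centerline samples
carrying position, radius, and unit tangent. For a trial atom the model
cross-section is an isotropic 2D Gaussian of FWHM $2r$ in the plane
perpendicular to the tangent, convolved with the marginal distribution
of the PSF in that plane (covariances add):

$$C(r) = \sigma_r^2 I_2 + E\,\Sigma_{PSF}(z)\,E^{\mathsf T},$$

where the rows of $E$ span the perpendicular plane. Eight spokes at
equally spaced plane angles extend from the centre; the fitted metric is
the sum over spokes of the inward radial intensity derivative at the
spoke tip, and position (in-plane) and radius are optimized by
alternating a bounded line search over the radius with quadratic
refinement of the in-plane offset.

Two numerical choices matter here:

* **Tip contour.** Tips are placed on the $1\sigma$ (inflection)
  contour of the model Gaussian, where the intensity profile along each
  ray — itself Gaussian with scale $1/\sqrt{u^{\mathsf T} C^{-1} u}$ —
  has maximal gradient. With this choice the summed-gradient metric is
  maximized exactly at the true radius, in every perpendicular
  direction simultaneously, for Gaussian tubes. Placing tips on the
  half-maximum contour instead (a natural-looking alternative, and the
  contour `boundaryEllipse` reports for display) biases the fitted
  radius low by 15–20% for mid-size vessels, because the half-max
  contour sits at $\sqrt{2\ln 2}\,\sigma$ where the gradient argument
  no longer matches.
* **Gradient estimator.** The radial derivative is a central difference
  with half-step 0.75 um of Catmull–Rom cubic-interpolated intensity.
  Cubic interpolation is essential: trilinear sampling quantizes the
  gradient field to voxel cells and locks the fitted boundary onto grid
  positions. The finite difference itself shifts the gradient argmax
  of a Gaussian ray of scale $s$ outward by a known factor $c(s) > 1$;
  the package computes $c(s)$ once per session from the exact argmax of
  the continuous central difference and places tips at the corrected
  distance, keeping the estimator consistent. A residual phase-dependent
  interpolation error of a few percent remains for vessels whose image
  scale is near one voxel and is largest for tubes exactly aligned with
  a grid axis; obliquely oriented vessels — the realistic case — are
  essentially unaffected.

Seeds are thresholded local maxima with respect to the six face
neighbours (threshold manual or Otsu), processed in order of decreasing
intensity; seeds inside previously traced vessels are skipped via an
occupancy mask dilated by the local radius. Chains march bidirectionally
in 1.5 um steps, the tangent exponentially smoothed (weight 0.5) over
successive centres, and the in-plane recentring per step is capped at
0.6 steps so chains do not slide into side branches at junctions.
Tracing stops when the metric falls below a fraction (default 0.1) of
the image's robust gradient scale (a high quantile of absolute voxel
differences, times the number of spokes), when the chain leaves the
volume, or when it enters occupied voxels. Spokes whose gradient falls
below half the median spoke gradient emit branch candidates (a dark
gap in the boundary indicates a vessel leaving it); candidates are
traced after the parent chain, starting just outside the parent
boundary. Chains are linked into a graph by joining chain endpoints to
the nearest vertex of another chain within the endpoint radius plus one
step.

Free-end *hairs* — boundary-noise artifacts — are pruned: a free-end
segment is removed when its arc length does not exceed the radius of
the vessel it attaches to by more than 8 um, iterated to a fixed point;
degree-2 junctions left behind dissolve when segments are rebuilt.

`recomputeDiameters` holds positions and tangents fixed and
re-optimizes only the radius under an alternative PSF model. This is
both the instrument for quantifying the constant-PSF error
(`psfBiasExperiment`: diameters tracked with the depth-varying model
versus re-measured under a constant 3.4 um axial assumption — the
difference exceeds 7% for vessels below 5 um and grows with depth,
shrinks with diameter) and the way warped ex vivo trees are re-measured
in in vivo space.

## Registration and comparison

Corresponding trees are registered by an interpolating 3D thin plate
spline with the biharmonic kernel $U(r) = r$, fitted to manually
identified landmark pairs (bifurcations). The transform reproduces the
landmarks exactly; affine landmark configurations give zero bending
energy. TPS has no closed-form inverse, so the practical inverse is the
spline fitted on swapped pairs — exact at landmarks and, for smooth
warps, sub-micrometre inside the landmark hull. At least 5 non-coplanar
pairs are required; degenerate configurations are rejected.

The ex vivo tree is warped into in vivo space, the ex vivo image is
resampled there (`warpVolume`, inverse mapping), and the warped tree's
diameters are re-measured in that image with the depth-constant PSF.
Vertices are paired by mutual nearest neighbours within 3 um (2 voxels;
mutual to avoid many-to-one collapse), and `compareDiameters` reports
per-segment ex/in diameter ratios with class labels and class-wise
summaries.

Morphometry follows the field's conventions: a *segment* is the piece
of network between bifurcations and/or free ends; its radius is the
mean of its vertex radii and its diameter twice that. *Penetrating*
vessels are traced from a surface marker by repeatedly taking, at each
junction, the outgoing segment making the smallest angle with the
cortical surface normal, stopping at a free end. *Capillaries* are
non-penetrating segments below 8 um diameter. Signals are normalized so
the mean over segments wider than 10 um is 1. The characteristic
attenuation length fits $\ln(\text{signal})$ against depth with the
two-photon convention $S \propto e^{-2z/\ell}$ (detected fluorescence
decays at twice the excitation rate; the single-exponent convention is
available as a flag). Perfusion uses the contrast-to-noise ratio
(vertex signal minus mean background, over the background standard
deviation): a segment is unperfused when more than 50% of its vertices
have CNR below 1.0 — the "approaches zero" cut-off is a package choice,
exposed in `morphometryConfig`. The perfusion rule is applied per
*segment* (the natural unit of our graph model; whether it should be
the whole connected tree is ambiguous, and segment is the conservative
reading). Shadowing labels vertices lying in the xy projection of
*pial* segments (shallower than 50 um, wider than 10 um, dilated by
their radii); those bounds are package defaults standing in for the
visual identification used with real data.

## The phantom generator

Every stage is validated against synthetic volumes with known ground
truth, because no public reference stacks exist for this preparation.

* Tubes are painted as Gaussian cross-section profiles (FWHM equal to
  the local diameter — the same model the tracker assumes; a hard-disk
  profile is available for model-mismatch experiments), then convolved
  with the PSF. The depth-varying axial convolution is piecewise
  constant over z slabs of at most 10 um (the width varies by < 0.05 um
  across a slab). Depth attenuation $e^{-2z/\ell}$ and shadow-polygon
  transmission factors multiply the *convolved* intensities — the
  order that makes two identical tubes at depths $z_{1,2}$ have a peak
  ratio of exactly $e^{-2(z_2-z_1)/\ell}$ — and noise is applied last.
  Default noise is additive Gaussian with sd 5% of the peak tube
  intensity, matching the contrast regime the denoising stage assumes.
* Beads are rendered analytically (Gaussian-equivalent bead of FWHM
  equal to the bead diameter, combined with the PSF at the bead's
  depth in quadrature), which keeps sub-voxel bead profiles exact.
* `randomTubeLayout` produces plausible cortical layouts: oblique
  capillary-calibre tubes with a minimum mutual separation, optional
  near-vertical penetrating-style tubes, and Y-branches budding off
  parents. Benchmarks use oblique orientations and continuous sub-voxel
  positions because real vessels are not grid aligned; exactly
  axis-aligned tubes at pathological sub-voxel phases are the worst
  case for any grid-based estimator and are exercised separately in
  unit tests.
* `makePairedPhantom` renders the same scene twice: once as the in vivo
  image, once mapped through a smooth warp with per-tube diameters
  transformed by a supplied scale function and the ex vivo PSF. The
  ground-truth networks correspond vertex by vertex and the bifurcation
  landmarks come out in both coordinate systems.

What the phantoms do *not* emulate: red-blood-cell motion, hematocrit
or wavelength-dependent scattering (shadows are a purely geometric
transmission factor), tissue autofluorescence, motion artifacts, or
stitching seams. Passing the phantom benchmarks therefore demonstrates
the correctness of the geometry, PSF handling and statistics, not
robustness to every nuisance in real stacks.

## Problem sizes and determinism

The validation suite runs entirely on synthetic data built at test
time: single-tube volumes of about $48^3$ voxels ($72\,\mu m$ cubes),
a 20-tube network benchmark in a $180 \times 180 \times 120\,\mu m$
volume (about 1.2 M voxels), 40-bead calibration stacks spanning
1 mm of depth, and a registered in vivo / ex vivo pair with 8 tubes.
These sizes keep each benchmark in the minutes range on a single core
while leaving the measured quantities (diameter errors, recall,
calibration slopes) in the asymptotic regime — larger phantoms change
the numbers by less than the reported tolerances. All generators take
explicit seeds; identical spec plus seed renders bit-identical volumes,
and generator functions restore the caller's RNG state.

## Known limitations

* Diameters below about 2.5 um (under two voxels at the standard grid)
  are at the edge of what the gradient estimator can localize; the
  residual interpolation bias is a few percent there and phase
  dependent for grid-aligned vessels.
* The tracker assumes bright tubes on a dark background after
  conditioning; it has no model of hollow (unperfused-core) vessels.
* The boundary model is a convolved Gaussian; strongly non-circular
  cross-sections (collapsed vessels) violate it.
* TPS accuracy degrades outside the landmark hull; landmarks should
  bracket the tissue of interest.
* The perfusion CNR rule needs a user-supplied background threshold, as
  with the manual threshold selection used in practice.
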
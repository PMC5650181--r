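Package: vesseltrace
Title: PSF-Aware Vessel Tracing and In Vivo/Ex Vivo Vascular Network
    Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for tracing the 3D cerebral microvasculature in
    two-photon fluorescence image stacks and for comparing vascular
    networks imaged in vivo and ex vivo. Implements medial-atom
    centerline tracking with an anisotropic, depth-varying Gaussian
    point-spread-function model (as arises when imaging optically
    cleared tissue with a water-immersion objective), bead-stack PSF
    calibration, refractive-index axial rescaling, the standard image
    conditioning chain (2D Gaussian blur, isotropic resampling,
    non-local-means denoising), thin-plate-spline landmark registration
    of vessel trees between image spaces, and network morphometry
    (segment decomposition, capillary and penetrating-vessel
    classification, perfusion contrast-to-noise scoring, shadow
    labeling, signal-attenuation fits, and matched diameter
    comparison). A synthetic phantom generator provides tube and bead
    volumes with known ground truth for validation.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    minpack.lm,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
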
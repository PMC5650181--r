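# Depth-varying PSF model: evaluation, marginalization perpendicular to a
# vessel axis, bead-stack calibration, refractive axial scaling.

#' Axial PSF FWHM at a given depth
#'
#' Evaluates the linear axial model `axialFwhm0 + axialSlope * depth`.
#'
#' @param model A [PSFModel-class].
#' @param depth Depth below the cortical surface, um (>= 0); vectorized.
#' @return Axial FWHM in um.
#' @examples
#' axialFwhmAtDepth(PSFModel(axialFwhm0 = 3.4, axialSlope = 0.0041), 1000)
#' @export
axialFwhmAtDepth <- function(model, depth) {
  if (any(depth < 0)) stop("depth must be >= 0")
  f <- model@axialFwhm0 + model@axialSlope * depth
  if (any(f <= 0)) stop("axial FWHM not positive over the requested depth")
  f
}

#' Axial scale factor from a refractive-index pair
#'
#' The apparent axial step of a stack acquired in a medium of index
#' `nAgent` through optics index-matched to `nWater` must be multiplied by
#' `nAgent/nWater` to recover true distances (1.49/1.33 = 1.12 for
#' fructose clearing under a water-immersion objective).
#'
#' @param r A [RefractiveScaling-class].
#' @return The dimensionless scale factor `nAgent / nWater`.
#' @export
axialScaleFactor <- function(r) {
  stopifnot(methods::is(r, "RefractiveScaling"))
  r@nAgent / r@nWater
}

## 3D PSF covariance (diagonal, um^2) at a given depth.
psfCovariance3 <- function(model, depth) {
  sl <- fwhmToSigma(model@lateralFwhm)
  sz <- fwhmToSigma(axialFwhmAtDepth(model, depth))
  diag(c(sl^2, sl^2, sz^2))
}

#' Marginal PSF covariance in the plane perpendicular to a vessel axis
#'
#' Marginalizing a zero-mean 3D Gaussian over the tangent direction leaves
#' a 2D Gaussian in the perpendicular plane whose covariance is
#' `E Sigma E^T`, with the rows of `E` an orthonormal basis of that plane.
#'
#' @param model A [PSFModel-class].
#' @param depth Depth below the surface, um.
#' @param tangent Unit 3-vector along the vessel axis.
#' @return List with `covariance` (2x2, um^2), `basis` (2x3 matrix of
#'   in-plane axes), and `fwhm` (eigen-FWHMs of the marginal, um).
#' @export
marginalPsfCovariance <- function(model, depth, tangent) {
  nt <- sqrt(sum(tangent^2))
  if (nt < 1e-8) stop("tangent must be non-zero")
  if (abs(nt - 1) > 1e-6) tangent <- tangent / nt
  E <- perpBasis(tangent)
  C <- E %*% psfCovariance3(model, depth) %*% t(E)
  C <- (C + t(C)) / 2
  list(covariance = C, basis = E,
       fwhm = sigmaToFwhm(sqrt(sort(eigen(C, symmetric = TRUE)$values))))
}

#' Effective PSF after the 2D preprocessing blur
#'
#' Tracking operates on images blurred laterally with a fixed-FWHM 2D
#' Gaussian; the effective lateral PSF width is the quadrature sum of the
#' optical lateral FWHM and the blur FWHM. The axial model is unchanged.
#'
#' @param model Optical [PSFModel-class].
#' @param blurFwhm FWHM (um) of the 2D conditioning blur.
#' @return A [PSFModel-class] describing the blurred image.
#' @export
effectivePsf <- function(model, blurFwhm = 1.5) {
  PSFModel(lateralFwhm = sqrt(model@lateralFwhm^2 + blurFwhm^2),
           axialFwhm0 = model@axialFwhm0, axialSlope = model@axialSlope)
}

#' Fit a 1D Gaussian to a bead profile
#'
#' Refines the bead centre by centre-of-mass in a 7^3-voxel window, then
#' extracts the intensity profile through the refined centre along the
#' requested axis and fits amplitude, centre, sigma and baseline by
#' nonlinear least squares. FWHM = 2*sqrt(2*log 2)*sigma. The volume is
#' expected to carry the same pre-blur as the vascular images the
#' calibration will serve.
#'
#' @param volume An [ImageVolume-class] containing the bead.
#' @param centerGuess World position (um) within ~2 voxels of the bead.
#' @param axis `"x"` or `"z"`: the profile direction.
#' @param halfWidth Half-extent of the profile, um.
#' @return List with `fwhm`, `sigma`, `center` (refined 3-point, um),
#'   `depth`, `amplitude`, `baseline`, `residual` (RMS / amplitude).
#' @export
fitBeadFwhm <- function(volume, centerGuess, axis = c("z", "x"),
                        halfWidth = 12) {
  axis <- match.arg(axis)
  v <- volume@voxels
  d <- dim(v)
  g <- round(worldToVoxel(volume, centerGuess))
  g <- pmin(pmax(g, 1), matrix(d, nrow = 1))
  w <- 3L
  ir <- max(1, g[1] - w):min(d[1], g[1] + w)
  jr <- max(1, g[2] - w):min(d[2], g[2] + w)
  kr <- max(1, g[3] - w):min(d[3], g[3] + w)
  blk <- v[ir, jr, kr, drop = FALSE]
  blk <- blk - min(blk)
  tot <- sum(blk)
  if (tot <= .Machine$double.eps * length(blk) || max(blk) <= 0)
    stop("no bead signal near centerGuess")
  gr <- expand.grid(i = ir, j = jr, k = kr)
  com <- colSums(gr * as.numeric(blk)) / tot
  center <- volume@origin + (as.numeric(com) - 1) * volume@voxelSize
  ax <- if (axis == "x") 1L else 3L
  h <- volume@voxelSize[ax]
  ## sample at voxel-centre positions along the axis (the Gaussian's
  ## centre is a free fit parameter, so no sub-voxel sampling is needed
  ## along the axis; interpolating along it would widen narrow
  ## profiles), interpolating only across the perpendicular directions.
  ## absolute world coordinates along the axis: keeps the fitted centre
  ## parameter well away from 0, where finite-difference model
  ## derivatives degenerate
  cAx <- volume@origin[ax] + round((center[ax] - volume@origin[ax]) / h) * h
  t <- cAx + seq(-round(halfWidth / h), round(halfWidth / h)) * h
  pts <- matrix(rep(center, each = length(t)), ncol = 3)
  pts[, ax] <- t
  y <- sampleIntensity(volume, pts)
  if (diff(range(y)) <= 1e-9 * max(abs(y), 1))
    stop("flat profile: no peak to fit")
  a0 <- max(y) - min(y)
  m0 <- t[which.max(y)]
  nAbove <- sum(y > min(y) + a0 / 2)
  s0 <- min(max(h / 2, nAbove * h / fwhmConstant()), halfWidth / 3)
  fit <- NULL
  for (jit in c(0.1, -0.35, 0.6)) {
    fit <- tryCatch(minpack.lm::nlsLM(
      y ~ b + a * exp(-(t - m)^2 / (2 * s^2)),
      start = list(a = a0, m = m0 + jit * h, s = s0 * (1 + jit),
                   b = min(y) + 1e-3 * a0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("Gaussian profile fit failed to converge")
  cf <- stats::coef(fit)
  if (cf[["a"]] <= 0 || abs(cf[["s"]]) <= 0)
    stop("Gaussian fit did not find a peak")
  center[ax] <- cf[["m"]]
  resid <- sqrt(mean(stats::resid(fit)^2)) / cf[["a"]]
  list(fwhm = sigmaToFwhm(abs(cf[["s"]])), sigma = abs(cf[["s"]]),
       center = unname(center), depth = center[3] - volume@surfaceZ,
       amplitude = cf[["a"]], baseline = cf[["b"]], residual = resid)
}

#' Calibrate the depth-varying PSF model from bead fits
#'
#' Ordinary least squares of axial FWHM against depth gives the linear
#' axial model; the lateral FWHMs are regressed on depth to test whether
#' their slope differs from 0 (it should not for a well-aligned system),
#' and if not, the lateral FWHM is set to their mean.
#'
#' @param beadFits data.frame with columns `depth`, `fwhm_x`, `fwhm_z`
#'   (um), e.g. rows assembled from [fitBeadFwhm()] results.
#' @param alpha Significance level for the lateral slope test.
#' @return List with `model` (a [PSFModel-class]), `axialFit` (lm),
#'   `axialConfint` (95% CI on intercept/slope), `lateralSlopeP`,
#'   `lateralMean`.
#' @export
calibratePsfDepthModel <- function(beadFits, alpha = 0.05) {
  beadFits <- as.data.frame(beadFits)
  stopifnot(all(c("depth", "fwhm_x", "fwhm_z") %in% names(beadFits)))
  if (nrow(beadFits) < 5)
    stop("need at least 5 bead fits")
  if (length(unique(round(beadFits$depth, 6))) < 3)
    stop("bead fits must span at least 3 distinct depths")
  fz <- stats::lm(fwhm_z ~ depth, data = beadFits)
  fx <- stats::lm(fwhm_x ~ depth, data = beadFits)
  pz <- stats::coef(fz)
  px <- summary(fx)$coefficients
  pLat <- px["depth", "Pr(>|t|)"]
  latMean <- mean(beadFits$fwhm_x)
  if (pLat < alpha)
    warning(sprintf(paste("lateral FWHM slope differs from 0 (p = %.3g);",
                          "reporting the fitted lateral line"), pLat))
  model <- PSFModel(lateralFwhm = latMean,
                    axialFwhm0 = unname(pz[1]),
                    axialSlope = unname(pz[2]))
  list(model = model, axialFit = fz,
       axialConfint = stats::confint(fz),
       lateralFit = fx, lateralSlopeP = unname(pLat),
       lateralMean = latMean)
}

#' Serialize / read a PSF model as a small YAML file
#'
#' @param model A [PSFModel-class].
#' @param path File path.
#' @param refractive Optional [RefractiveScaling-class] stored alongside.
#' @return `readPSFModel` returns a list with `model` and (if present)
#'   `refractive`.
#' @export
writePSFModel <- function(model, path, refractive = NULL) {
  rec <- list(lateral_fwhm_um = model@lateralFwhm,
              axial_fwhm0_um = model@axialFwhm0,
              axial_slope_um_per_um = model@axialSlope)
  if (!is.null(refractive)) {
    rec$n_agent <- refractive@nAgent
    rec$n_water <- refractive@nWater
  }
  yaml::write_yaml(rec, path)
  invisible(path)
}

#' @rdname writePSFModel
#' @export
readPSFModel <- function(path) {
  rec <- yaml::read_yaml(path)
  out <- list(model = PSFModel(lateralFwhm = rec$lateral_fwhm_um,
                               axialFwhm0 = rec$axial_fwhm0_um,
                               axialSlope = rec$axial_slope_um_per_um))
  if (!is.null(rec$n_agent))
    out$refractive <- RefractiveScaling(rec$n_agent, rec$n_water)
  out
}
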
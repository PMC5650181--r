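# Shared numerical helpers: FWHM conversions, grid geometry, separable
# convolution with reflect padding, trilinear sampling, thresholding.

#' Gaussian FWHM/sigma conversion constant
#'
#' All widths in the package follow the Gaussian convention
#' FWHM = 2*sqrt(2*log(2)) * sigma.
#' @return The conversion constant (about 2.3548).
#' @export
fwhmConstant <- function() 2 * sqrt(2 * log(2))

#' @rdname fwhmConstant
#' @param fwhm Full width at half maximum.
#' @export
fwhmToSigma <- function(fwhm) fwhm / fwhmConstant()

#' @rdname fwhmConstant
#' @param sigma Gaussian standard deviation.
#' @export
sigmaToFwhm <- function(sigma) sigma * fwhmConstant()

## Reflect (mirror) out-of-range indices into 1..n.
reflectIndex <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  i <- (i - 1L) %% p
  i <- ifelse(i < 0L, i + p, i)
  as.integer(ifelse(i >= n, p - i, i) + 1L)
}

## Discrete Gaussian kernel whose *discrete* second moment equals
## sigma^2, so that chained convolutions add variances exactly as the
## continuous quadrature rule predicts. For sub-voxel sigma a 3-tap
## exact-variance kernel is used; otherwise the sampled Gaussian's scale
## is adjusted until the discrete variance matches.
gaussKernel <- function(sigma, h = 1) {
  if (sigma <= 0) return(1)
  s <- sigma / h
  if (s < 0.5) {
    a <- s^2 / 2
    return(c(a, 1 - 2 * a, a))
  }
  r <- max(2L, ceiling(4 * s) + 1L)
  i <- (-r):r
  s2 <- s^2
  for (it in 1:8) {
    k <- exp(-i^2 / (2 * s2))
    k <- k / sum(k)
    v <- sum(k * i^2)
    if (abs(v - s^2) < 1e-10) break
    s2 <- max(s2 + (s^2 - v), 1e-6)
  }
  k
}

## Take slices of a 3D array along one axis (keeps dims).
sliceTake <- function(v, idx, axis) {
  switch(axis,
         v[idx, , , drop = FALSE],
         v[, idx, , drop = FALSE],
         v[, , idx, drop = FALSE])
}

## Separable convolution of a 3D array along one axis, reflect padding.
convAxis <- function(v, kernel, axis) {
  nk <- length(kernel)
  if (nk == 1L) return(v * kernel)
  d <- dim(v)
  n <- d[axis]
  r <- (nk - 1L) %/% 2L
  out <- array(0, d)
  base <- seq_len(n)
  for (t in seq_len(nk)) {
    src <- reflectIndex(base + (t - 1L - r), n)
    out <- out + kernel[t] * sliceTake(v, src, axis)
  }
  out
}

## Convolution along z with a depth-dependent sigma (in voxel units),
## piecewise constant over groups of z indices. sigmaByZ: numeric length nz.
## Groups are formed by rounding sigma to `quant` voxels.
convZVarying <- function(v, sigmaByZ, quant = 1e-3) {
  d <- dim(v)
  nz <- d[3]
  stopifnot(length(sigmaByZ) == nz)
  out <- array(0, d)
  key <- round(sigmaByZ / quant)
  base <- seq_len(nz)
  for (k in unique(key)) {
    zs <- base[key == k]
    kern <- gaussKernel(sigmaByZ[zs[1]], h = 1)
    r <- (length(kern) - 1L) %/% 2L
    acc <- array(0, c(d[1], d[2], length(zs)))
    for (t in seq_along(kern)) {
      src <- reflectIndex(zs + (t - 1L - r), nz)
      acc <- acc + kern[t] * v[, , src, drop = FALSE]
    }
    out[, , zs] <- acc
  }
  out
}

## Trilinear interpolation at continuous 1-based voxel coordinates.
## pts: n x 3 matrix. Coordinates are clamped to the volume.
interpTrilinear <- function(v, pts) {
  d <- dim(v)
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  x <- pmin(pmax(pts[, 1], 1), d[1])
  y <- pmin(pmax(pts[, 2], 1), d[2])
  z <- pmin(pmax(pts[, 3], 1), d[3])
  i0 <- pmin(floor(x), max(d[1] - 1L, 1L)); fx <- x - i0
  j0 <- pmin(floor(y), max(d[2] - 1L, 1L)); fy <- y - j0
  k0 <- pmin(floor(z), max(d[3] - 1L, 1L)); fz <- z - k0
  i1 <- pmin(i0 + 1, d[1]); j1 <- pmin(j0 + 1, d[2]); k1 <- pmin(k0 + 1, d[3])
  v[cbind(i0, j0, k0)] * (1 - fx) * (1 - fy) * (1 - fz) +
    v[cbind(i1, j0, k0)] * fx * (1 - fy) * (1 - fz) +
    v[cbind(i0, j1, k0)] * (1 - fx) * fy * (1 - fz) +
    v[cbind(i1, j1, k0)] * fx * fy * (1 - fz) +
    v[cbind(i0, j0, k1)] * (1 - fx) * (1 - fy) * fz +
    v[cbind(i1, j0, k1)] * fx * (1 - fy) * fz +
    v[cbind(i0, j1, k1)] * (1 - fx) * fy * fz +
    v[cbind(i1, j1, k1)] * fx * fy * fz
}

## Catmull-Rom cubic interpolation at continuous 1-based voxel
## coordinates; C1-continuous, so radial intensity derivatives sampled
## from it vary smoothly (trilinear sampling quantizes boundary
## positions to the voxel grid). Border nodes are clamped.
interpCubic <- function(v, pts) {
  d <- dim(v)
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  crWeights <- function(f) {
    cbind((-f^3 + 2 * f^2 - f) / 2,
          (3 * f^3 - 5 * f^2 + 2) / 2,
          (-3 * f^3 + 4 * f^2 + f) / 2,
          (f^3 - f^2) / 2)
  }
  ax <- vector("list", 3)
  for (k in 1:3) {
    x <- pmin(pmax(pts[, k], 1), d[k])
    i0 <- pmin(floor(x), max(d[k] - 1L, 1L))
    f <- x - i0
    idx <- cbind(i0 - 1, i0, i0 + 1, i0 + 2)
    idx[idx < 1] <- 1
    idx[idx > d[k]] <- d[k]
    ax[[k]] <- list(idx = idx, w = crWeights(f))
  }
  out <- numeric(nrow(pts))
  for (a in 1:4) for (b in 1:4) {
    wab <- ax[[1]]$w[, a] * ax[[2]]$w[, b]
    ia <- ax[[1]]$idx[, a]; jb <- ax[[2]]$idx[, b]
    for (cc in 1:4) {
      out <- out + wab * ax[[3]]$w[, cc] *
        v[cbind(ia, jb, ax[[3]]$idx[, cc])]
    }
  }
  out
}

## Calibration of the spoke-tip placement against the finite-difference
## estimator's deterministic shift: the radial gradient is measured by
## a central difference with half-step hVox (voxel units), and for a
## Gaussian ray profile of scale s the argmax of that estimator sits at
## c(s) * s with c(s) > 1 (largest for s near hVox). c(s) is the exact
## argmax of the continuous h-difference, computed once per session and
## cached; spoke tips are placed at the corrected distance so the
## radius estimator stays consistent under the difference scheme.
.vtCache <- new.env(parent = emptyenv())

tipCorrectionFun <- function(hVox = 0.5) {
  key <- sprintf("tipcorr_%.4f", hVox)
  if (!is.null(.vtCache[[key]])) return(.vtCache[[key]])
  sGrid <- seq(0.3, 8, by = 0.05)
  cVal <- vapply(sGrid, function(s) {
    stats::optimize(function(t)
      exp(-(t - hVox)^2 / (2 * s^2)) - exp(-(t + hVox)^2 / (2 * s^2)),
      interval = c(max(0.2 * s, hVox * 0.2), 3 * s),
      maximum = TRUE, tol = 1e-5)$maximum / s
  }, 1)
  fn <- stats::approxfun(sGrid, cVal, rule = 2)
  .vtCache[[key]] <- fn
  fn
}

#' Otsu intensity threshold
#'
#' Histogram-based two-class threshold maximizing between-class variance;
#' used as the automatic seed threshold separating vessel foreground from
#' tissue background.
#'
#' @param x Numeric vector or array of intensities.
#' @param nbins Number of histogram bins.
#' @return Threshold on the intensity scale of `x`.
#' @export
otsuThreshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  rng <- range(x, finite = TRUE)
  if (diff(rng) <= 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[nbins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bc <- rep(-Inf, nbins)
  bc[valid] <- (muT * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  mids[which.max(bc)]
}

## Robust noise-sd estimate from 6-neighbour pseudo-residuals
## r = (6 v - sum of face neighbours)/sqrt(42); sd = MAD-scaled median.
estimateNoiseSd <- function(v) {
  d <- dim(v)
  acc <- 6 * v
  for (ax in 1:3) {
    n <- d[ax]
    acc <- acc - sliceTake(v, reflectIndex(seq_len(n) + 1L, n), ax)
    acc <- acc - sliceTake(v, reflectIndex(seq_len(n) - 1L, n), ax)
  }
  r <- as.numeric(acc) / sqrt(42)
  stats::median(abs(r)) / 0.6745
}

## Orthonormal basis of the plane perpendicular to a unit tangent.
perpBasis <- function(tangent) {
  t <- tangent / sqrt(sum(tangent^2))
  ref <- if (abs(t[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- c(t[2] * ref[3] - t[3] * ref[2],
          t[3] * ref[1] - t[1] * ref[3],
          t[1] * ref[2] - t[2] * ref[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(t[2] * e1[3] - t[3] * e1[2],
          t[3] * e1[1] - t[1] * e1[3],
          t[1] * e1[2] - t[2] * e1[1])
  unname(rbind(e1, e2))
}

## Distance from points P (n x 3) to segment [a, b]; returns list(d2, t).
pointSegmentDistance <- function(P, a, b) {
  ab <- b - a
  L2 <- sum(ab^2)
  if (L2 < .Machine$double.eps) {
    dd <- sweep(P, 2, a)
    return(list(d2 = rowSums(dd^2), t = rep(0, nrow(P))))
  }
  t <- (sweep(P, 2, a) %*% ab)[, 1] / L2
  t <- pmin(pmax(t, 0), 1)
  cl <- cbind(a[1] + t * ab[1], a[2] + t * ab[2], a[3] + t * ab[3])
  list(d2 = rowSums((P - cl)^2), t = t)
}
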
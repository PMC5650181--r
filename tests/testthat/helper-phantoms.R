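# Shared fixtures, generated in code: single-tube volumes, simple
# graphs, smooth warps.

ISO <- c(1.5, 1.5, 1.5)

# Ex vivo optical PSF (pre-blur) and its effective version on the
# conditioned image; in vivo variants are depth-constant.
psfOptical <- function() PSFModel(lateralFwhm = 1.0)
psfTracking <- function() effectivePsf(psfOptical(), 1.5)
psfConstTracking <- function()
  PSFModel(lateralFwhm = lateralFwhm(psfTracking()),
           axialFwhm0 = 3.4, axialSlope = 0)

# A straight tube of diameter d whose centre sits at the requested
# cortical depth, rendered in its own small volume and lateral-blurred
# as in the tracking chain. Orientation: xy angle `ang` (tube is
# horizontal). Returns volume, centreline endpoints, centre, direction.
tubeVolume <- function(d, depth = 0, ang = 0.4, off = 0.37,
                       shape = c(48, 48, 36), peak = 100,
                       noise = list(type = "none"), psf = psfOptical(),
                       blur = 1.5, seed = 1L) {
  ctr <- (shape - 1) * ISO / 2 + c(off, off, off * 0.7)
  dir <- c(cos(ang), sin(ang), 0)
  cl <- rbind(ctr - 90 * dir, ctr + 90 * dir)
  spec <- phantomSpec(shape, ISO, list(tubeSpec(cl, d, peak)),
                      surfaceZ = ctr[3] - depth, noise = noise,
                      seed = seed)
  vol <- suppressWarnings(renderVesselPhantom(spec, psf))$volume
  if (!is.null(blur)) vol <- blurXY(vol, blur)
  list(volume = vol, cl = cl, center = ctr, dir = dir, spec = spec)
}

# Hand-built small network: vertices on a polyline (plus optional extra
# branches), radius constant.
pathNetwork <- function(coords, radius = 2, edges = NULL) {
  n <- nrow(coords)
  v <- data.frame(id = seq_len(n), x = coords[, 1], y = coords[, 2],
                  z = coords[, 3], radius = radius,
                  signal = 1, depth = coords[, 3])
  if (is.null(edges)) edges <- cbind(seq_len(n - 1), seq_len(n - 1) + 1)
  buildSegments(VesselNetwork(v, edges))
}

# Smooth synthetic warp for TPS tests: translation + gentle quadratic
# bend, invertible on the test domain.
smoothWarp <- function(p) {
  p <- if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
  cbind(p[, 1] + 5 + 3e-4 * (p[, 2] - 50)^2,
        p[, 2] - 3 + 2.5e-4 * (p[, 1] - 50)^2,
        p[, 3] + 2 + 2e-4 * (p[, 1] - 50) * (p[, 2] - 50) / 10)
}

# Landmarks scattered through a box (jittered grid, non-coplanar).
boxLandmarks <- function(n = 20, extent = c(100, 100, 100), seed = 5) {
  set.seed(seed)
  cbind(runif(n) * extent[1], runif(n) * extent[2], runif(n) * extent[3])
}

# Squared distance from point(s) to a segment, independent of the
# package's internal helper (used as a geometric oracle).
pointSegmentDistanceTest <- function(P, a, b) {
  if (is.null(dim(P))) P <- matrix(P, ncol = 3)
  ab <- b - a
  tt <- pmin(pmax((sweep(P, 2, a) %*% ab) / sum(ab^2), 0), 1)
  cl <- cbind(a[1] + tt * ab[1], a[2] + tt * ab[2], a[3] + tt * ab[3])
  rowSums((P - cl)^2)
}

# Mean vertex depth per segment, from public accessors only.
segMeanDepthTest <- function(net) {
  vt <- vertexTable(net)
  vapply(segmentPaths(net), function(p)
    mean(vt$depth[match(p, vt$id)]), 1)
}

# Uniform arc-length resampling of a polyline (straight segments).
resamplePolylineTest <- function(cl, spacing = 1) {
  out <- NULL
  for (s in seq_len(nrow(cl) - 1)) {
    a <- cl[s, ]; b <- cl[s + 1, ]
    L <- sqrt(sum((b - a)^2))
    tt <- seq(0, 1, length.out = max(2, ceiling(L / spacing) + 1))
    out <- rbind(out, sweep(outer(tt, b - a), 2, a, "+"))
  }
  out
}

# Random tree network with 3D coordinates for graph-rule oracles.
randomTreeNetwork <- function(nJunctions = 6, seed = 1) {
  set.seed(seed)
  # grow a random tree downward from a root
  pos <- matrix(c(50, 50, 0), 1)
  parent <- c(NA_integer_)
  for (v in 2:(3 * nJunctions + 2)) {
    p <- sample(nrow(pos), 1)
    dir <- c(rnorm(2, 0, 0.6), abs(rnorm(1, 1, 0.3)))
    dir <- dir / sqrt(sum(dir^2))
    pos <- rbind(pos, pos[p, ] + dir * runif(1, 8, 20))
    parent <- c(parent, p)
  }
  n <- nrow(pos)
  v <- data.frame(id = seq_len(n), x = pos[, 1], y = pos[, 2],
                  z = pos[, 3], radius = runif(n, 1.5, 4),
                  signal = 1, depth = pos[, 3])
  edges <- cbind(2:n, parent[2:n])
  buildSegments(VesselNetwork(v, edges))
}
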
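# Medial-atom vessel tracking with a PSF-aware elliptical boundary
# model: seed selection, atom fitting, bidirectional tracing with branch
# detection, network assembly, hair pruning, diameter recomputation.

#' Tracker configuration
#'
#' @param seedThreshold Intensity threshold separating vessel foreground
#'   from background when placing seeds; `"auto"` uses Otsu's method.
#' @param stepLength Marching step along the vessel, um (1 voxel of the
#'   standard isotropic grid).
#' @param radiusBounds Allowed fitted radius interval, um.
#' @param branchGradientFraction Spokes whose gradient falls below this
#'   fraction of the median spoke gradient emit branch candidates.
#' @param terminationMetricFraction Tracing stops when the atom metric
#'   drops below this fraction of the image's robust gradient scale
#'   (summed over 8 spokes).
#' @param hairAllowance Free-end pruning allowance, um: a free-end
#'   segment is removed when its length does not exceed the radius of the
#'   vessel it attaches to by more than this amount.
#' @param initRadius Initial radius guess for new chains, um.
#' @param maxSteps Maximum atoms per direction per chain.
#' @param nSpokes Number of boundary spokes.
#' @return A validated `TrackerConfig` list.
#' @export
trackerConfig <- function(seedThreshold = "auto", stepLength = 1.5,
                          radiusBounds = c(0.6, 20),
                          branchGradientFraction = 0.5,
                          terminationMetricFraction = 0.1,
                          hairAllowance = 8, initRadius = 2.5,
                          maxSteps = 4000L, nSpokes = 8L) {
  stopifnot(length(radiusBounds) == 2L, radiusBounds[1] > 0,
            radiusBounds[1] < radiusBounds[2],
            branchGradientFraction > 0, branchGradientFraction < 1,
            terminationMetricFraction > 0, stepLength > 0,
            hairAllowance >= 0)
  structure(list(seedThreshold = seedThreshold, stepLength = stepLength,
                 radiusBounds = radiusBounds,
                 branchGradientFraction = branchGradientFraction,
                 terminationMetricFraction = terminationMetricFraction,
                 hairAllowance = hairAllowance, initRadius = initRadius,
                 maxSteps = as.integer(maxSteps),
                 nSpokes = as.integer(nSpokes)),
            class = "TrackerConfig")
}

#' Construct a medial atom
#'
#' A centerline sample of a tubular structure: position, radius, unit
#' tangent, local signal and depth, plus the last evaluated spoke
#' gradients and metric.
#'
#' @param position World position, um.
#' @param radius Vessel radius, um.
#' @param tangent Unit 3-vector along the vessel.
#' @param signal Image intensity at the position.
#' @param depth Depth below the cortical surface, um.
#' @param spokeGradients Numeric vector of spoke gradients.
#' @param metric Summed spoke-gradient metric.
#' @return A `MedialAtom` list.
#' @export
medialAtom <- function(position, radius, tangent, signal = NA_real_,
                       depth = NA_real_, spokeGradients = numeric(),
                       metric = NA_real_) {
  tangent <- tangent / sqrt(sum(tangent^2))
  structure(list(position = as.numeric(position), radius = radius,
                 tangent = tangent, signal = signal, depth = depth,
                 spokeGradients = spokeGradients, metric = metric),
            class = "MedialAtom")
}

shiftPad <- function(v, off, axis, pad = -Inf) {
  d <- dim(v)
  n <- d[axis]
  src <- seq_len(n) + off
  ok <- src >= 1L & src <= n
  out <- array(pad, d)
  idxOut <- seq_len(n)[ok]
  switch(axis,
         out[idxOut, , ] <- v[src[ok], , , drop = FALSE],
         out[, idxOut, ] <- v[, src[ok], , drop = FALSE],
         out[, , idxOut] <- v[, , src[ok], drop = FALSE])
  out
}

#' Select tracking seeds
#'
#' Seeds are voxels above the threshold that are local intensity maxima
#' with respect to their six face neighbours. Ties between equal
#' neighbouring maxima are broken toward the lowest linear index; border
#' voxels are compared against in-bounds neighbours only.
#'
#' @param volume An [ImageVolume-class].
#' @param threshold Intensity threshold, or `"auto"` for Otsu.
#' @return data.frame with voxel indices (i, j, k), world coordinates
#'   (x, y, z) and intensity.
#' @export
selectSeeds <- function(volume, threshold = "auto") {
  v <- volume@voxels
  if (identical(threshold, "auto")) threshold <- otsuThreshold(v)
  ok <- v > threshold
  for (ax in 1:3) {
    ok <- ok & (v > shiftPad(v, -1L, ax)) & (v >= shiftPad(v, +1L, ax))
  }
  w <- which(ok)
  d <- dim(v)
  ij <- arrayInd(w, d)
  data.frame(i = ij[, 1], j = ij[, 2], k = ij[, 3],
             x = volume@origin[1] + (ij[, 1] - 1) * volume@voxelSize[1],
             y = volume@origin[2] + (ij[, 2] - 1) * volume@voxelSize[2],
             z = volume@origin[3] + (ij[, 3] - 1) * volume@voxelSize[3],
             intensity = v[w])
}

#' PSF-convolved boundary ellipse of a vessel cross-section
#'
#' The circular vessel cross-section (2D Gaussian, FWHM = 2 radius) is
#' convolved with the marginal PSF in the plane perpendicular to the
#' tangent; covariances add. The returned contour radii are those of the
#' requested level set of the resulting 2D Gaussian: `"halfmax"` gives
#' the half-maximum ellipse, `"sigma"` the 1-sigma (inflection /
#' maximum-gradient) ellipse on which spoke tips are placed during
#' fitting.
#'
#' @param radius Vessel radius, um.
#' @param tangent Unit tangent 3-vector.
#' @param depth Depth below the surface, um.
#' @param psf A [PSFModel-class].
#' @param contour `"halfmax"` or `"sigma"`.
#' @return List with `covariance` (2x2 um^2 in the perpendicular plane),
#'   `basis` (2x3 plane axes), `axes` (2x2 eigenvectors), `contourRadii`
#'   (um, sorted increasing) and `fwhm` (eigen-FWHMs of the convolved
#'   Gaussian).
#' @export
boundaryEllipse <- function(radius, tangent, depth, psf,
                            contour = c("halfmax", "sigma")) {
  contour <- match.arg(contour)
  mp <- marginalPsfCovariance(psf, depth, tangent)
  sr <- fwhmToSigma(2 * radius)
  C <- sr^2 * diag(2) + mp$covariance
  eg <- eigen(C, symmetric = TRUE)
  scale <- if (contour == "halfmax") sqrt(2 * log(2)) else 1
  list(covariance = C, basis = mp$basis, axes = eg$vectors,
       contourRadii = sort(scale * sqrt(eg$values)),
       fwhm = sort(sigmaToFwhm(sqrt(eg$values))))
}

## Spoke tips and radial directions for an atom. Tips sit on the
## 1-sigma (maximum-gradient) contour of the model Gaussian, scaled by
## the measurement-chain correction factor (see tipCorrectionFun).
spokeGeometry <- function(position, tangent, radius, depth, psf,
                          nSpokes = 8L, voxel = 1.5, h = 0.75) {
  E <- perpBasis(tangent)
  mp <- psfCovariance3(psf, max(depth, 0))
  C <- fwhmToSigma(2 * radius)^2 * diag(2) + E %*% mp %*% t(E)
  phi <- 2 * pi * (seq_len(nSpokes) - 1) / nSpokes
  u <- cbind(cos(phi), sin(phi))
  ## radius of the 1-sigma contour ellipse along each ray: the intensity
  ## profile along a ray through an anisotropic Gaussian has exactly this
  ## sigma, so the boundary gradient peaks there when the model matches.
  Ci <- solve(C)
  dist <- 1 / sqrt(rowSums((u %*% Ci) * u))
  cf <- tipCorrectionFun(h / voxel)(dist / voxel)
  dist <- dist * cf
  dirs <- u %*% E
  tips <- sweep(dirs * dist, 2, position, "+")
  list(tips = tips, dirs = dirs, dist = dist)
}

#' Spoke-gradient metric of a medial atom
#'
#' Each spoke contributes the inward radial derivative of the
#' (trilinearly interpolated) intensity at its tip on the boundary
#' ellipse; the metric is their sum. Spokes whose sample points fall
#' outside the volume contribute 0 and are flagged.
#'
#' @param volume An [ImageVolume-class].
#' @param atom A [medialAtom()].
#' @param psf A [PSFModel-class].
#' @param nSpokes Number of spokes.
#' @param h Finite-difference half-step, um.
#' @return List with `total`, `perSpoke`, and `outOfBounds` flags.
#' @export
atomMetric <- function(volume, atom, psf, nSpokes = 8L, h = 0.75) {
  depth <- atom$position[3] - volume@surfaceZ
  sg <- spokeGeometry(atom$position, atom$tangent, atom$radius, depth,
                      psf, nSpokes, voxel = mean(volume@voxelSize), h = h)
  inner <- sg$tips - h * sg$dirs
  outer <- sg$tips + h * sg$dirs
  pts <- rbind(inner, outer)
  vc <- worldToVoxel(volume, pts)
  d <- dim(volume@voxels)
  oob <- vc[, 1] < 1 | vc[, 1] > d[1] | vc[, 2] < 1 | vc[, 2] > d[2] |
    vc[, 3] < 1 | vc[, 3] > d[3]
  vals <- interpCubic(volume@voxels, vc)
  g <- (vals[seq_len(nSpokes)] - vals[nSpokes + seq_len(nSpokes)]) / (2 * h)
  bad <- oob[seq_len(nSpokes)] | oob[nSpokes + seq_len(nSpokes)]
  g[bad] <- 0
  list(total = sum(g), perSpoke = g, outOfBounds = bad)
}

## Metric as a function of radius / in-plane offset for one atom.
atomMetricAt <- function(volume, position, tangent, radius, psf, nSpokes) {
  atomMetric(volume,
             medialAtom(position, radius, tangent),
             psf, nSpokes = nSpokes)$total
}

#' Fit a medial atom
#'
#' Alternates a bounded line search over the radius with quadratic
#' refinement of the in-plane centre offset, maximizing the spoke
#' gradient metric; the tangent is held fixed (it is re-estimated from
#' neighbouring centres during tracing).
#'
#' @param volume An [ImageVolume-class].
#' @param init A [medialAtom()] giving the starting position, radius and
#'   tangent.
#' @param psf A [PSFModel-class].
#' @param config A [trackerConfig()].
#' @param rounds Alternation rounds.
#' @param maxShift Cap (um) on the total in-plane recentring away from
#'   the initial position; during marching this keeps the chain from
#'   sliding into side branches at junctions.
#' @return The fitted [medialAtom()] with signal, depth, spoke gradients
#'   and metric filled in.
#' @export
fitAtom <- function(volume, init, psf, config = trackerConfig(),
                    rounds = 3L, maxShift = Inf) {
  pos <- init$position
  tangent <- init$tangent
  r <- min(max(init$radius, config$radiusBounds[1]), config$radiusBounds[2])
  E <- perpBasis(tangent)
  s <- 0.5 * min(volume@voxelSize)
  for (it in seq_len(rounds)) {
    lo <- max(config$radiusBounds[1], 0.4 * r)
    hi <- min(config$radiusBounds[2], 2.5 * r)
    opt <- stats::optimize(function(rr)
      atomMetricAt(volume, pos, tangent, rr, psf, config$nSpokes),
      interval = c(lo, hi), maximum = TRUE, tol = 0.01)
    r <- opt$maximum
    grid <- expand.grid(u = c(-s, 0, s), w = c(-s, 0, s))
    m <- vapply(seq_len(nrow(grid)), function(q) {
      p <- pos + grid$u[q] * E[1, ] + grid$w[q] * E[2, ]
      atomMetricAt(volume, p, tangent, r, psf, config$nSpokes)
    }, 1)
    cf <- stats::lm.fit(cbind(1, grid$u, grid$w, grid$u^2, grid$w^2,
                              grid$u * grid$w), m)$coefficients
    H <- matrix(c(2 * cf[4], cf[6], cf[6], 2 * cf[5]), 2)
    step <- NULL
    if (all(is.finite(H)) && H[1, 1] < 0 && det(H) > 0) {
      step <- -solve(H, c(cf[2], cf[3]))
      if (sqrt(sum(step^2)) > 1.5 * s) step <- NULL
    }
    if (is.null(step)) {
      best <- which.max(m)
      step <- c(grid$u[best], grid$w[best])
    }
    cand <- pos + step[1] * E[1, ] + step[2] * E[2, ]
    if (is.finite(maxShift)) {
      dd <- cand - init$position
      dn <- sqrt(sum(dd^2))
      if (dn > maxShift) cand <- init$position + dd * (maxShift / dn)
    }
    pos <- cand
  }
  met <- atomMetric(volume, medialAtom(pos, r, tangent), psf,
                    nSpokes = config$nSpokes)
  medialAtom(pos, r, tangent,
             signal = sampleIntensity(volume, matrix(pos, 1)),
             depth = pos[3] - volume@surfaceZ,
             spokeGradients = met$perSpoke, metric = met$total)
}

#' Robust gradient scale of a volume
#'
#' High quantile of the absolute intensity derivative (per um) along the
#' grid axes; the tracker's termination threshold is a fraction of this
#' scale summed over the spokes.
#'
#' @param volume An [ImageVolume-class].
#' @param probs Quantile used.
#' @return Scalar gradient scale (intensity per um).
#' @export
robustGradientScale <- function(volume, probs = 0.995) {
  v <- volume@voxels
  d <- dim(v)
  g <- c()
  for (ax in 1:3) {
    if (d[ax] < 2) next
    dif <- abs(sliceTake(v, 2:d[ax], ax) -
                 sliceTake(v, seq_len(d[ax] - 1L), ax)) /
      volume@voxelSize[ax]
    g <- c(g, as.numeric(dif))
  }
  if (length(g) > 1e6) g <- g[seq(1, length(g), length.out = 1e6)]
  as.numeric(stats::quantile(g, probs))
}

metricThreshold <- function(volume, config) {
  config$terminationMetricFraction * config$nSpokes *
    robustGradientScale(volume)
}

## Principal direction of a tubular structure near a point: eigenvector
## of the smallest eigenvalue of the local gradient structure tensor.
localTangent <- function(volume, pWorld, windowVox = 2L) {
  v <- volume@voxels
  d <- dim(v)
  g <- round(worldToVoxel(volume, pWorld))
  if (anyNA(g) || any(!is.finite(g))) return(c(1, 0, 0))
  g <- pmin(pmax(as.integer(g), 1L), d)
  w <- windowVox + 1L
  rngAx <- function(ax) {
    lo <- max(2L, g[ax] - w); hi <- min(d[ax] - 1L, g[ax] + w)
    if (lo > hi) integer() else lo:hi
  }
  ir <- rngAx(1); jr <- rngAx(2); kr <- rngAx(3)
  if (!length(ir) || !length(jr) || !length(kr)) return(c(1, 0, 0))
  gx <- (v[ir + 1, jr, kr, drop = FALSE] -
           v[ir - 1, jr, kr, drop = FALSE]) / (2 * volume@voxelSize[1])
  gy <- (v[ir, jr + 1, kr, drop = FALSE] -
           v[ir, jr - 1, kr, drop = FALSE]) / (2 * volume@voxelSize[2])
  gz <- (v[ir, jr, kr + 1, drop = FALSE] -
           v[ir, jr, kr - 1, drop = FALSE]) / (2 * volume@voxelSize[3])
  G <- cbind(as.numeric(gx), as.numeric(gy), as.numeric(gz))
  J <- crossprod(G)
  if (!all(is.finite(J)) || sum(abs(J)) < 1e-12) return(c(1, 0, 0))
  eg <- eigen(J, symmetric = TRUE)
  eg$vectors[, 3]
}

occupiedAt <- function(occ, volume, pWorld) {
  d <- dim(occ)
  g <- round(worldToVoxel(volume, pWorld))
  if (any(g < 1) || any(g > d)) return(FALSE)
  occ[g[1], g[2], g[3]] > 0L
}

markOccupancy <- function(occ, volume, atoms, chainId) {
  d <- dim(occ)
  for (a in atoms) {
    rVox <- a$radius / volume@voxelSize
    g <- worldToVoxel(volume, a$position)
    ir <- max(1, floor(g[1] - rVox[1])):min(d[1], ceiling(g[1] + rVox[1]))
    jr <- max(1, floor(g[2] - rVox[2])):min(d[2], ceiling(g[2] + rVox[2]))
    kr <- max(1, floor(g[3] - rVox[3])):min(d[3], ceiling(g[3] + rVox[3]))
    if (!length(ir) || !length(jr) || !length(kr)) next
    gg <- expand.grid(i = ir, j = jr, k = kr)
    pw <- cbind(volume@origin[1] + (gg$i - 1) * volume@voxelSize[1],
                volume@origin[2] + (gg$j - 1) * volume@voxelSize[2],
                volume@origin[3] + (gg$k - 1) * volume@voxelSize[3])
    keep <- rowSums(sweep(pw, 2, a$position)^2) <= max(a$radius,
                                                       min(volume@voxelSize))^2
    sel <- as.matrix(gg[keep, , drop = FALSE])
    if (nrow(sel)) occ[sel] <- chainId
  }
  occ
}

#' Trace a vessel chain from a seed
#'
#' Marches bidirectionally from the seed in steps of `stepLength` along
#' the running tangent (exponentially smoothed from successive centres),
#' fitting a medial atom at each step. Tracing stops on the termination
#' signal (metric below threshold), on leaving the volume, or on entering
#' voxels occupied by previously traced vessels. Spokes whose gradient
#' falls below `branchGradientFraction` times the median spoke gradient
#' emit branch candidates.
#'
#' @param volume An [ImageVolume-class].
#' @param seed World position (um) of the seed (numeric length 3).
#' @param psf A [PSFModel-class].
#' @param config A [trackerConfig()].
#' @param occupancy Optional integer array of previously traced voxels.
#' @param initialTangent Optional starting tangent; otherwise estimated
#'   from the local gradient structure tensor.
#' @param threshold Metric termination threshold; computed from the
#'   volume when `NULL`.
#' @return `NULL` if no atom could be fitted at the seed, else a list
#'   with `atoms` (list of [medialAtom()]) and `branches` (data.frame of
#'   candidate branch points x, y, z).
#' @export
traceFromSeed <- function(volume, seed, psf, config = trackerConfig(),
                          occupancy = NULL, initialTangent = NULL,
                          threshold = NULL) {
  if (is.null(threshold)) threshold <- metricThreshold(volume, config)
  if (!is.null(occupancy) && occupiedAt(occupancy, volume, seed))
    return(NULL)
  t0 <- initialTangent %||% localTangent(volume, seed)
  a0 <- fitAtom(volume, medialAtom(seed, config$initRadius, t0),
                psf, config)
  if (!is.finite(a0$metric) || a0$metric < threshold) return(NULL)
  branches <- list()
  walk <- function(dir0) {
    atoms <- list()
    d <- dir0
    prev <- a0
    for (k in seq_len(config$maxSteps)) {
      pred <- prev$position + config$stepLength * d
      vc <- worldToVoxel(volume, pred)
      if (any(vc < 1) || any(vc > dim(volume@voxels))) break
      if (!is.null(occupancy) && occupiedAt(occupancy, volume, pred)) break
      a <- fitAtom(volume, medialAtom(pred, prev$radius, d), psf, config,
                   maxShift = 0.6 * config$stepLength)
      if (!is.finite(a$metric) || a$metric < threshold) break
      stepv <- (a$position - prev$position)
      nst <- sqrt(sum(stepv^2))
      if (nst > 1e-9) {
        d <- 0.5 * d + 0.5 * stepv / nst
        d <- d / sqrt(sum(d^2))
      }
      atoms[[length(atoms) + 1L]] <- a
      md <- stats::median(a$spokeGradients)
      low <- which(a$spokeGradients < config$branchGradientFraction * md &
                     !is.na(a$spokeGradients))
      if (length(low) && md > 0) {
        sg <- spokeGeometry(a$position, a$tangent, a$radius,
                            max(a$depth, 0), psf, config$nSpokes,
                            voxel = mean(volume@voxelSize))
        for (li in low) {
          ## branch point estimate = atom centre; trace start = just
          ## outside the boundary along the low-gradient spoke
          branches[[length(branches) + 1L]] <<-
            c(a$position, sg$tips[li, ] + 1.0 * sg$dirs[li, ])
        }
      }
      prev <- a
    }
    atoms
  }
  fwd <- walk(a0$tangent)
  bwd <- walk(-a0$tangent)
  atoms <- c(rev(bwd), list(a0), fwd)
  br <- if (length(branches))
    as.data.frame(do.call(rbind, branches)) else
      data.frame(x = numeric(), y = numeric(), z = numeric(),
                 seed_x = numeric(), seed_y = numeric(),
                 seed_z = numeric())
  names(br) <- c("x", "y", "z", "seed_x", "seed_y", "seed_z")
  list(atoms = atoms, branches = br)
}

#' Track all vessels in a volume
#'
#' Places seeds at thresholded local maxima, processes them in order of
#' decreasing intensity (seeds inside already-traced vessels are
#' ignored), traces chains with branch-candidate follow-up, links chains
#' into a network with junction nodes, builds segments and prunes hairs.
#'
#' @param volume A preprocessed [ImageVolume-class].
#' @param psf The [PSFModel-class] describing the image (effective PSF
#'   of the conditioned data).
#' @param config A [trackerConfig()].
#' @return A [VesselNetwork-class] with segments built and hairs pruned.
#' @export
trackImage <- function(volume, psf, config = trackerConfig()) {
  seeds <- selectSeeds(volume, config$seedThreshold)
  if (nrow(seeds) == 0) {
    warning("no seeds above threshold; returning empty network")
    return(buildSegments(VesselNetwork()))
  }
  seeds <- seeds[order(-seeds$intensity), , drop = FALSE]
  thr <- metricThreshold(volume, config)
  occ <- array(0L, dim(volume@voxels))
  chains <- list()
  addChain <- function(res) {
    chains[[length(chains) + 1L]] <<- res$atoms
    occ <<- markOccupancy(occ, volume, res$atoms, length(chains))
  }
  branchQueue <- list()
  traceBranches <- function(depthLeft) {
    while (length(branchQueue)) {
      cand <- branchQueue[[1]]
      branchQueue <<- branchQueue[-1]
      if (occupiedAt(occ, volume, cand)) next
      res <- traceFromSeed(volume, cand, psf, config, occ,
                           threshold = thr)
      if (is.null(res) || length(res$atoms) < 3) next
      inOcc <- vapply(res$atoms, function(a)
        occupiedAt(occ, volume, a$position), TRUE)
      if (mean(inOcc) > 0.5) next
      addChain(res)
      if (depthLeft > 0 && nrow(res$branches))
        for (q in seq_len(nrow(res$branches)))
          branchQueue[[length(branchQueue) + 1L]] <<-
            as.numeric(res$branches[q, c("seed_x", "seed_y", "seed_z")])
    }
  }
  for (si in seq_len(nrow(seeds))) {
    sp <- as.numeric(seeds[si, c("x", "y", "z")])
    if (occupiedAt(occ, volume, sp)) next
    res <- traceFromSeed(volume, sp, psf, config, occ, threshold = thr)
    if (is.null(res) || length(res$atoms) < 2) next
    addChain(res)
    if (nrow(res$branches))
      for (q in seq_len(nrow(res$branches)))
        branchQueue[[length(branchQueue) + 1L]] <-
          as.numeric(res$branches[q, c("seed_x", "seed_y", "seed_z")])
    traceBranches(depthLeft = 8L)
  }
  net <- chainsToNetwork(chains, volume, config)
  if (nrow(net@vertices) == 0) {
    warning("no vessels traced")
    return(buildSegments(net))
  }
  net <- buildSegments(net)
  pruneHairs(net, config$hairAllowance)
}

## Assemble chains into a VesselNetwork, linking endpoints to nearby
## vertices of other chains (junction creation).
chainsToNetwork <- function(chains, volume, config) {
  if (!length(chains)) return(VesselNetwork())
  rows <- list(); edges <- list(); off <- 0L
  chainOf <- integer()
  endIdx <- list()
  for (ci in seq_along(chains)) {
    atoms <- chains[[ci]]
    n <- length(atoms)
    df <- data.frame(
      id = off + seq_len(n),
      x = vapply(atoms, function(a) a$position[1], 1),
      y = vapply(atoms, function(a) a$position[2], 1),
      z = vapply(atoms, function(a) a$position[3], 1),
      radius = vapply(atoms, `[[`, 1, "radius"),
      tx = vapply(atoms, function(a) a$tangent[1], 1),
      ty = vapply(atoms, function(a) a$tangent[2], 1),
      tz = vapply(atoms, function(a) a$tangent[3], 1),
      signal = vapply(atoms, `[[`, 1, "signal"),
      depth = vapply(atoms, `[[`, 1, "depth"),
      segment_id = NA_integer_, cnr = NA_real_, label = "unset",
      stringsAsFactors = FALSE)
    rows[[ci]] <- df
    if (n > 1)
      edges[[ci]] <- cbind(off + seq_len(n - 1L), off + seq_len(n - 1L) + 1L)
    chainOf <- c(chainOf, rep(ci, n))
    endIdx[[ci]] <- c(off + 1L, off + n)
    off <- off + n
  }
  verts <- do.call(rbind, rows)
  E <- if (length(edges)) do.call(rbind, edges) else
    matrix(integer(), ncol = 2)
  ## endpoint linking across chains
  P <- as.matrix(verts[, c("x", "y", "z")])
  for (ci in seq_along(chains)) {
    for (ei in endIdx[[ci]]) {
      tol <- verts$radius[ei] + config$stepLength
      dd <- sqrt(rowSums(sweep(P, 2, P[ei, ])^2))
      dd[chainOf == ci] <- Inf
      j <- which.min(dd)
      if (is.finite(dd[j]) && dd[j] <= tol)
        E <- rbind(E, c(verts$id[ei], verts$id[j]))
    }
  }
  E <- unique(t(apply(E, 1, sort)))
  if (!is.matrix(E)) E <- matrix(E, ncol = 2)
  E <- E[E[, 1] != E[, 2], , drop = FALSE]
  VesselNetwork(verts, E)
}

#' Prune hair artifacts
#'
#' Removes every free-end segment whose arc length does not exceed the
#' radius of the vessel it attaches to (at the junction) by more than the
#' allowance (8 um by default), repeating to a fixed point; junctions
#' left with degree 2 dissolve into their parent segment when segments
#' are rebuilt.
#'
#' @param network A [VesselNetwork-class] (segments will be rebuilt).
#' @param hairAllowance Allowance in um.
#' @return The pruned network with segments rebuilt.
#' @export
pruneHairs <- function(network, hairAllowance = 8) {
  repeat {
    network <- buildSegments(network)
    seg <- network@segments
    if (!nrow(seg)) return(network)
    paths <- network@segmentPaths
    deg <- vertexDegrees(network)
    remove <- integer()
    for (si in seq_len(nrow(seg))) {
      p <- paths[[si]]
      d1 <- deg[as.character(p[1])]
      d2 <- deg[as.character(p[length(p)])]
      free1 <- d1 == 1; free2 <- d2 == 1
      if (xor(free1, free2)) {
        junc <- if (free1) p[length(p)] else p[1]
        if (deg[as.character(junc)] < 3) next
        parentR <- parentRadiusAt(network, si, junc)
        if (seg$arc_length[si] <= parentR + hairAllowance)
          remove <- c(remove, si)
      }
    }
    if (!length(remove)) return(network)
    keepEdges <- !(edgeSegmentIds(network) %in% remove)
    network@edges <- network@edges[keepEdges, , drop = FALSE]
    used <- unique(as.integer(network@edges))
    network@vertices <- network@vertices[network@vertices$id %in% used |
                                           !(network@vertices$id %in%
                                               unlist(paths[remove])), ,
                                         drop = FALSE]
    network@segments <- data.frame()
    network@segmentPaths <- list()
  }
}

## Mean radius of the largest other segment incident at a junction.
parentRadiusAt <- function(network, segIdx, junctionId) {
  paths <- network@segmentPaths
  rr <- c()
  for (si in seq_along(paths)) {
    if (si == segIdx) next
    p <- paths[[si]]
    if (p[1] == junctionId || p[length(p)] == junctionId)
      rr <- c(rr, network@segments$mean_radius[si])
  }
  if (!length(rr)) return(0)
  max(rr)
}

#' Recompute vertex diameters under an assumed PSF
#'
#' Holds every vertex position and tangent fixed and re-optimizes only
#' the radius with the given PSF model. Used to quantify the error made
#' by assuming a depth-constant PSF, and to re-measure warped trees in a
#' target image space.
#'
#' @param network A [VesselNetwork-class].
#' @param volume The [ImageVolume-class] in whose space the network lies.
#' @param psfAssumed The [PSFModel-class] to assume.
#' @param config A [trackerConfig()] (radius bounds).
#' @return The network with updated radii (vertices outside the volume
#'   get `NA` radius); segment statistics are rebuilt if present.
#' @export
recomputeDiameters <- function(network, volume, psfAssumed,
                               config = trackerConfig()) {
  verts <- network@vertices
  d <- dim(volume@voxels)
  for (q in seq_len(nrow(verts))) {
    pos <- as.numeric(verts[q, c("x", "y", "z")])
    vc <- worldToVoxel(volume, pos)
    if (any(vc < 1) || any(vc > d)) {
      verts$radius[q] <- NA_real_
      next
    }
    tangent <- as.numeric(verts[q, c("tx", "ty", "tz")])
    if (anyNA(tangent) || sum(tangent^2) < 1e-12) tangent <- c(1, 0, 0)
    r <- verts$radius[q]
    if (!is.finite(r)) r <- config$initRadius
    for (it in 1:2) {
      lo <- max(config$radiusBounds[1], 0.4 * r)
      hi <- min(config$radiusBounds[2], 2.5 * r)
      r <- stats::optimize(function(rr)
        atomMetricAt(volume, pos, tangent, rr, psfAssumed,
                     config$nSpokes),
        interval = c(lo, hi), maximum = TRUE, tol = 0.005)$maximum
    }
    verts$radius[q] <- r
  }
  network@vertices <- verts
  if (nrow(network@segments)) network <- buildSegments(network)
  network
}
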
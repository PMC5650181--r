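# Synthetic phantoms: tube volumes with ground-truth networks, bead
# stacks for PSF calibration, and matched in vivo / ex vivo pairs.

#' Specify a synthetic vessel tube
#'
#' @param centerline Matrix (>= 2 x 3) of ordered 3D points, um,
#'   continuous world coordinates.
#' @param diameter Tube diameter in um; scalar or one value per
#'   centerline point (linearly interpolated along the path).
#' @param peakIntensity Pre-convolution centre intensity.
#' @param profile `"gaussian"` (cross-section Gaussian with
#'   FWHM = diameter, the tracker's model) or `"disk"` (hard cylinder,
#'   for model-mismatch experiments).
#' @return A `TubeSpec` list.
#' @export
tubeSpec <- function(centerline, diameter, peakIntensity = 1,
                     profile = c("gaussian", "disk")) {
  profile <- match.arg(profile)
  centerline <- as.matrix(centerline)
  if (nrow(centerline) < 2 || ncol(centerline) != 3)
    stop("centerline must be at least 2 points x 3 coordinates")
  if (any(diameter <= 0)) stop("diameter must be > 0")
  if (!length(diameter) %in% c(1L, nrow(centerline)))
    stop("diameter must be scalar or one value per centerline point")
  structure(list(centerline = centerline,
                 diameter = rep(diameter, length.out = nrow(centerline)),
                 peakIntensity = peakIntensity, profile = profile),
            class = "TubeSpec")
}

#' Specify a vessel phantom volume
#'
#' @param volumeShape Integer triple: voxels along x, y, z.
#' @param voxelSize um per voxel, length 1 or 3.
#' @param tubes List of [tubeSpec()] objects.
#' @param backgroundLevel Constant background intensity.
#' @param noise `list(type = "none")`, `list(type = "gaussian", sd = )`
#'   (sd defaults to 5% of the maximum tube peak), or
#'   `list(type = "poisson", scale = )`.
#' @param attenuationLength Characteristic attenuation length ell (um):
#'   intensities are scaled by exp(-2 * depth / ell); `NULL` disables.
#' @param shadowRegions List of `list(polygon = , transmission = ,
#'   minDepth = )`: xy polygons (n x 2 matrices, um) whose enclosed
#'   voxels (at depth > minDepth) are scaled by transmission in [0, 1].
#' @param surfaceZ World z of the cortical surface (depth reference).
#' @param origin World position of the first voxel centre.
#' @param seed RNG seed: identical spec + seed gives identical volumes.
#' @return A `PhantomSpec` list.
#' @export
phantomSpec <- function(volumeShape, voxelSize = c(1.5, 1.5, 1.5),
                        tubes = list(), backgroundLevel = 0,
                        noise = list(type = "none"),
                        attenuationLength = NULL,
                        shadowRegions = list(),
                        surfaceZ = 0, origin = c(0, 0, 0), seed = 1L) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3)
  if (any(volumeShape <= 0) || any(voxelSize <= 0))
    stop("volumeShape and voxelSize must be positive")
  for (s in shadowRegions) {
    if (s$transmission < 0 || s$transmission > 1)
      stop("shadow transmission factors must lie in [0, 1]")
  }
  if (!is.null(attenuationLength) && attenuationLength <= 0)
    stop("attenuationLength must be positive")
  structure(list(volumeShape = as.integer(volumeShape),
                 voxelSize = as.numeric(voxelSize), tubes = tubes,
                 backgroundLevel = backgroundLevel, noise = noise,
                 attenuationLength = attenuationLength,
                 shadowRegions = shadowRegions, surfaceZ = surfaceZ,
                 origin = as.numeric(origin), seed = as.integer(seed)),
            class = "PhantomSpec")
}

## Paint one tube into an accumulator array (max-combined), un-convolved.
paintTube <- function(acc, tube, voxelSize, origin, warnClip = TRUE) {
  d <- dim(acc)
  cl <- tube$centerline
  dia <- tube$diameter
  axesWorld <- lapply(1:3, function(ax)
    origin[ax] + (seq_len(d[ax]) - 1) * voxelSize[ax])
  lo <- origin - voxelSize / 2
  hi <- origin + (d - 0.5) * voxelSize
  if (warnClip &&
      (any(apply(cl, 1, function(p) any(p < lo | p > hi)))))
    warning("tube extends outside the volume; clipping")
  for (s in seq_len(nrow(cl) - 1)) {
    a <- cl[s, ]; b <- cl[s + 1, ]
    dmax <- max(dia[s], dia[s + 1])
    cut <- if (tube$profile == "gaussian")
      4 * fwhmToSigma(dmax) else dmax / 2 + max(voxelSize)
    rng <- lapply(1:3, function(ax) {
      which(axesWorld[[ax]] >= min(a[ax], b[ax]) - cut &
              axesWorld[[ax]] <= max(a[ax], b[ax]) + cut)
    })
    if (any(vapply(rng, length, 1L) == 0)) next
    P <- as.matrix(expand.grid(x = axesWorld[[1]][rng[[1]]],
                               y = axesWorld[[2]][rng[[2]]],
                               z = axesWorld[[3]][rng[[3]]]))
    ps <- pointSegmentDistance(P, a, b)
    diaT <- dia[s] + (dia[s + 1] - dia[s]) * ps$t
    val <- if (tube$profile == "gaussian") {
      sg <- fwhmToSigma(diaT)
      tube$peakIntensity * exp(-ps$d2 / (2 * sg^2))
    } else {
      tube$peakIntensity * as.numeric(ps$d2 <= (diaT / 2)^2)
    }
    blk <- acc[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    acc[rng[[1]], rng[[2]], rng[[3]]] <-
      pmax(blk, array(val, dim(blk)))
  }
  acc
}

## Convolve an array with the (possibly depth-varying) PSF.
applyPsfBlur <- function(v, psf, voxelSize, depths) {
  sl <- fwhmToSigma(psf@lateralFwhm)
  v <- convAxis(v, gaussKernel(sl / voxelSize[1]), 1L)
  v <- convAxis(v, gaussKernel(sl / voxelSize[2]), 2L)
  sz <- fwhmToSigma(axialFwhmAtDepth(psf, pmax(depths, 0))) / voxelSize[3]
  if (psf@axialSlope == 0) {
    v <- convAxis(v, gaussKernel(sz[1]), 3L)
  } else {
    slab <- 10 / voxelSize[3]          # <= 10 um slabs, piecewise constant
    group <- floor((seq_along(depths) - 1) / max(1, floor(slab)))
    szq <- stats::ave(sz, group)
    v <- convZVarying(v, szq, quant = 1e-9)
  }
  v
}

## Ground-truth network from tube specs: vertices at ~spacing um arc steps.
truthNetworkFromTubes <- function(tubes, spacing = 1.5, surfaceZ = 0) {
  verts <- list(); edges <- list(); off <- 0L
  for (ti in seq_along(tubes)) {
    tube <- tubes[[ti]]
    rs <- resamplePolyline(tube$centerline, tube$diameter, spacing)
    n <- nrow(rs$points)
    tg <- polylineTangents(rs$points)
    verts[[ti]] <- data.frame(
      id = off + seq_len(n),
      x = rs$points[, 1], y = rs$points[, 2], z = rs$points[, 3],
      radius = rs$diameter / 2,
      tx = tg[, 1], ty = tg[, 2], tz = tg[, 3],
      signal = NA_real_, depth = rs$points[, 3] - surfaceZ,
      segment_id = ti, cnr = NA_real_, label = "unset",
      stringsAsFactors = FALSE)
    if (n > 1)
      edges[[ti]] <- cbind(off + seq_len(n - 1), off + seq_len(n - 1) + 1)
    off <- off + n
  }
  VesselNetwork(do.call(rbind, verts),
                if (length(edges)) do.call(rbind, edges)
                else matrix(integer(), ncol = 2))
}

## Resample a polyline (with per-point diameter) at fixed arc spacing.
resamplePolyline <- function(cl, dia, spacing) {
  seg <- sqrt(rowSums(diff(cl)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  tt <- unique(c(seq(0, L, by = spacing), L))
  pts <- cbind(stats::approx(s, cl[, 1], tt)$y,
               stats::approx(s, cl[, 2], tt)$y,
               stats::approx(s, cl[, 3], tt)$y)
  dd <- stats::approx(s, dia, tt)$y
  list(points = pts, diameter = dd)
}

polylineTangents <- function(pts) {
  n <- nrow(pts)
  if (n == 1) return(matrix(c(1, 0, 0), 1))
  d <- rbind(pts[2, ] - pts[1, ],
             (pts[seq_len(max(n - 2, 0)) + 2, , drop = FALSE] -
                pts[seq_len(max(n - 2, 0)), , drop = FALSE]) / 2,
             pts[n, ] - pts[n - 1, ])
  d / sqrt(rowSums(d^2))
}

#' Render a vessel phantom
#'
#' Tubes are painted as Gaussian cross-section profiles (FWHM equal to the
#' local diameter) around their centerlines, convolved with the
#' depth-varying PSF (axial width evaluated per z slab), scaled by
#' exponential depth attenuation and by shadow-region transmission where
#' configured, and finally corrupted by the requested noise. The
#' companion ground-truth network samples each centerline with the true
#' radii.
#'
#' @param spec A [phantomSpec()].
#' @param psf A [PSFModel-class] used for the rendering blur.
#' @return List with `volume` (an [ImageVolume-class]) and `truth`
#'   (a [VesselNetwork-class]).
#' @export
renderVesselPhantom <- function(spec, psf) {
  stopifnot(inherits(spec, "PhantomSpec"))
  d <- spec$volumeShape
  acc <- array(0, d)
  for (tube in spec$tubes)
    acc <- paintTube(acc, tube, spec$voxelSize, spec$origin)
  depths <- spec$origin[3] + (seq_len(d[3]) - 1) * spec$voxelSize[3] -
    spec$surfaceZ
  v <- applyPsfBlur(acc, psf, spec$voxelSize, depths)
  if (!is.null(spec$attenuationLength)) {
    fac <- exp(-2 * pmax(depths, 0) / spec$attenuationLength)
    v <- sweep(v, 3, fac, "*")
  }
  if (length(spec$shadowRegions)) {
    xs <- spec$origin[1] + (seq_len(d[1]) - 1) * spec$voxelSize[1]
    ys <- spec$origin[2] + (seq_len(d[2]) - 1) * spec$voxelSize[2]
    xy <- as.matrix(expand.grid(x = xs, y = ys))
    for (s in spec$shadowRegions) {
      inside <- mgcv::in.out(rbind(as.matrix(s$polygon),
                                   as.matrix(s$polygon)[1, ]), xy)
      minDepth <- s$minDepth %||% 0
      zsel <- which(depths > minDepth)
      if (!length(zsel) || !any(inside)) next
      m <- matrix(1, d[1], d[2])
      m[inside] <- s$transmission
      v[, , zsel] <- v[, , zsel, drop = FALSE] *
        array(m, c(d[1], d[2], length(zsel)))
    }
  }
  v <- v + spec$backgroundLevel
  v <- applyPhantomNoise(v, spec)
  vol <- ImageVolume(v, spec$voxelSize, spec$origin, spec$surfaceZ,
                     provenance = list(list(step = "renderVesselPhantom",
                                            seed = spec$seed)))
  truth <- truthNetworkFromTubes(spec$tubes,
                                 spacing = min(spec$voxelSize),
                                 surfaceZ = spec$surfaceZ)
  list(volume = vol, truth = truth)
}

applyPhantomNoise <- function(v, spec) {
  noise <- spec$noise
  if (is.null(noise) || identical(noise$type, "none")) return(v)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)
  if (noise$type == "gaussian") {
    sd <- noise$sd
    if (is.null(sd)) {
      peaks <- vapply(spec$tubes, `[[`, 1, "peakIntensity")
      sd <- 0.05 * max(c(peaks, 1))
    }
    v <- v + stats::rnorm(length(v), sd = sd)
  } else if (noise$type == "poisson") {
    sc <- noise$scale %||% 1
    v <- array(stats::rpois(length(v), pmax(v, 0) * sc) / sc, dim(v))
  } else stop("unknown noise type: ", noise$type)
  pmax(v, 0)
}

#' Specify and render a bead phantom for PSF calibration
#'
#' Beads (Gaussian-equivalent profile, FWHM = bead diameter) are placed
#' uniformly at random over the volume with a minimum separation, and the
#' bead-PSF product is evaluated analytically at voxel centres using the
#' PSF at each bead's depth. The true centres are returned.
#'
#' @param nBeads Number of beads.
#' @param beadDiameter Bead diameter, um (0.5 for typical calibration
#'   beads).
#' @param depthRange Length-2 um interval of bead depths.
#' @param psf A [PSFModel-class].
#' @param volumeShape,voxelSize Volume geometry (voxels; um).
#' @param minSeparation Minimum distance between bead centres, um.
#' @param peakIntensity Pre-convolution bead peak.
#' @param noise As in [phantomSpec()].
#' @param seed RNG seed.
#' @return A `BeadPhantomSpec` list.
#' @export
beadPhantomSpec <- function(nBeads, beadDiameter = 0.5,
                            depthRange = c(0, 1000), psf = PSFModel(),
                            volumeShape = c(48, 48, 700),
                            voxelSize = c(1.5, 1.5, 1.5),
                            minSeparation = 25, peakIntensity = 1,
                            noise = list(type = "none"), seed = 1L) {
  if (beadDiameter <= 0) stop("beadDiameter must be > 0")
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3)
  zmax <- (volumeShape[3] - 1) * voxelSize[3]
  if (depthRange[1] < 0 || depthRange[2] > zmax)
    stop("depthRange lies outside the volume")
  structure(list(nBeads = as.integer(nBeads), beadDiameter = beadDiameter,
                 depthRange = depthRange, psf = psf,
                 volumeShape = as.integer(volumeShape),
                 voxelSize = voxelSize, minSeparation = minSeparation,
                 peakIntensity = peakIntensity, noise = noise,
                 seed = as.integer(seed)),
            class = "BeadPhantomSpec")
}

#' @rdname beadPhantomSpec
#' @param spec A `BeadPhantomSpec`.
#' @return `renderBeadPhantom` returns a list with `volume` and `beads`
#'   (data.frame x, y, z, depth of true centres).
#' @export
renderBeadPhantom <- function(spec) {
  stopifnot(inherits(spec, "BeadPhantomSpec"))
  d <- spec$volumeShape
  vs <- spec$voxelSize
  ext <- (d - 1) * vs
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)
  centers <- matrix(numeric(), 0, 3)
  guard <- 0L
  margin <- pmin(6, ext / 4)
  while (nrow(centers) < spec$nBeads && guard < 20000L) {
    guard <- guard + 1L
    p <- c(stats::runif(1, margin[1], ext[1] - margin[1]),
           stats::runif(1, margin[2], ext[2] - margin[2]),
           stats::runif(1, max(spec$depthRange[1], 0),
                        min(spec$depthRange[2], ext[3])))
    if (nrow(centers) == 0 ||
        min(sqrt(rowSums(sweep(centers, 2, p)^2))) >= spec$minSeparation)
      centers <- rbind(centers, p)
  }
  if (nrow(centers) < spec$nBeads)
    stop("could not place beads with the requested separation")
  v <- array(0, d)
  sb <- fwhmToSigma(spec$beadDiameter)
  sl <- fwhmToSigma(spec$psf@lateralFwhm)
  axes <- lapply(1:3, function(ax) (seq_len(d[ax]) - 1) * vs[ax])
  for (b in seq_len(nrow(centers))) {
    p <- centers[b, ]
    sz <- fwhmToSigma(axialFwhmAtDepth(spec$psf, p[3]))
    sx <- sqrt(sb^2 + sl^2); szz <- sqrt(sb^2 + sz^2)
    amp <- spec$peakIntensity * sb^3 / (sx * sx * szz)
    rng <- lapply(1:3, function(ax) {
      s <- if (ax == 3) szz else sx
      which(abs(axes[[ax]] - p[ax]) <= 5 * s)
    })
    if (any(vapply(rng, length, 1L) == 0)) next
    gx <- exp(-(axes[[1]][rng[[1]]] - p[1])^2 / (2 * sx^2))
    gy <- exp(-(axes[[2]][rng[[2]]] - p[2])^2 / (2 * sx^2))
    gz <- exp(-(axes[[3]][rng[[3]]] - p[3])^2 / (2 * szz^2))
    blk <- amp * outer(outer(gx, gy), gz)
    v[rng[[1]], rng[[2]], rng[[3]]] <-
      v[rng[[1]], rng[[2]], rng[[3]]] + blk
  }
  fake <- list(noise = spec$noise, seed = spec$seed, tubes = list())
  v <- applyPhantomNoise(v, fake)
  vol <- ImageVolume(v, vs, origin = c(0, 0, 0), surfaceZ = 0,
                     provenance = list(list(step = "renderBeadPhantom",
                                            seed = spec$seed)))
  beads <- if (nrow(centers)) {
    data.frame(x = centers[, 1], y = centers[, 2], z = centers[, 3],
               depth = centers[, 3])
  } else data.frame(x = numeric(), y = numeric(), z = numeric(),
                    depth = numeric())
  list(volume = vol, beads = beads)
}

#' Render a matched in vivo / ex vivo phantom pair
#'
#' The in vivo volume renders `spec` as given. The ex vivo volume is the
#' same geometry mapped through `warp` with per-tube diameters transformed
#' by `diameterScaleFn`, rendered with the (typically depth-varying) ex
#' vivo PSF and no attenuation, shadows or noise. Landmark pairs are the
#' bifurcation points of the in vivo truth (supplemented with tube
#' endpoints to reach at least 10) with their warped partners; the two
#' ground-truth networks correspond vertex by vertex.
#'
#' @param spec A [phantomSpec()] describing the in vivo scene.
#' @param warp Function mapping an n x 3 matrix of in vivo points to ex
#'   vivo points, or a [TPSTransform-class].
#' @param diameterScaleFn Function um -> um applied to tube diameters.
#' @param psfIn,psfEx PSF models for the two renders.
#' @return List with `inVivo`, `exVivo` (ImageVolumes), `truthIn`,
#'   `truthEx` (VesselNetworks), `landmarks` (data.frame x_in..z_ex), and
#'   `correspondence` (data.frame id_in, id_ex).
#' @export
makePairedPhantom <- function(spec, warp, diameterScaleFn = identity,
                              psfIn = PSFModel(axialSlope = 0),
                              psfEx = PSFModel()) {
  warpFn <- if (methods::is(warp, "TPSTransform"))
    function(p) tpsEval(warp, p) else warp
  rin <- renderVesselPhantom(spec, psfIn)
  exTubes <- lapply(spec$tubes, function(tube) {
    tubeSpec(warpFn(tube$centerline),
             vapply(tube$diameter, diameterScaleFn, 1),
             tube$peakIntensity, tube$profile)
  })
  exSpec <- phantomSpec(spec$volumeShape, spec$voxelSize, exTubes,
                        backgroundLevel = spec$backgroundLevel,
                        noise = list(type = "none"),
                        surfaceZ = spec$surfaceZ, origin = spec$origin,
                        seed = spec$seed)
  rex <- renderVesselPhantom(exSpec, psfEx)
  ## ex truth = in truth warped vertexwise: exact 1:1 correspondence
  vin <- vertexTable(rin$truth)
  vex <- vin
  Pex <- warpFn(as.matrix(vin[, c("x", "y", "z")]))
  vex$x <- Pex[, 1]; vex$y <- Pex[, 2]; vex$z <- Pex[, 3]
  vex$radius <- vapply(2 * vin$radius, diameterScaleFn, 1) / 2
  vex$depth <- vex$z - spec$surfaceZ
  truthEx <- VesselNetwork(vex, edgeTable(rin$truth))
  lmIn <- phantomLandmarks(spec$tubes)
  lmEx <- warpFn(lmIn)
  landmarks <- data.frame(x_in = lmIn[, 1], y_in = lmIn[, 2],
                          z_in = lmIn[, 3], x_ex = lmEx[, 1],
                          y_ex = lmEx[, 2], z_ex = lmEx[, 3])
  corr <- data.frame(id_in = vin$id, id_ex = vin$id)
  list(inVivo = rin$volume, exVivo = rex$volume,
       truthIn = rin$truth, truthEx = truthEx,
       landmarks = landmarks, correspondence = corr)
}

#' Random vascular tube layout
#'
#' Generates a plausible cortical-microvessel layout in a box: mostly
#' oblique capillary-calibre tubes plus optional near-vertical
#' penetrating-style tubes and Y-branches budding off parents, with a
#' minimum centerline separation between unrelated tubes.
#'
#' @param nTubes Number of primary (unbranched) tubes.
#' @param extent Box size in um (length 3); tubes span the box.
#' @param diameterRange Diameter interval (um) for primary tubes.
#' @param nPenetrating Number of near-vertical large tubes.
#' @param penetratingDiameter Diameter (um) of penetrating-style tubes.
#' @param nBranches Number of Y-branches grafted onto primary tubes.
#' @param minSeparation Minimum distance between unrelated centerlines.
#' @param peakIntensity Tube peak intensity.
#' @param seed RNG seed.
#' @return List with `tubes` (list of [tubeSpec()]) and `info`
#'   (data.frame: tube index, kind, diameter, parent).
#' @export
randomTubeLayout <- function(nTubes = 20, extent = c(180, 180, 120),
                             diameterRange = c(3, 8),
                             nPenetrating = 0, penetratingDiameter = 12,
                             nBranches = 0, minSeparation = 12,
                             peakIntensity = 100, seed = 1L) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  lineDist <- function(a1, b1, a2, b2) {
    s1 <- resamplePolyline(rbind(a1, b1), c(1, 1), 2)$points
    s2 <- resamplePolyline(rbind(a2, b2), c(1, 1), 2)$points
    min(vapply(seq_len(nrow(s1)), function(i)
      min(sqrt(rowSums(sweep(s2, 2, s1[i, ])^2))), 1))
  }
  tubes <- list(); info <- list(); lines <- list()
  mk <- function(kind) {
    for (try in 1:300) {
      if (kind == "penetrating") {
        p0 <- c(stats::runif(1, 0.2, 0.8) * extent[1],
                stats::runif(1, 0.2, 0.8) * extent[2], -5)
        dir <- c(stats::runif(2, -0.15, 0.15), 1)
        dia <- penetratingDiameter
      } else {
        p0 <- stats::runif(3) * extent
        az <- stats::runif(1, 0, 2 * pi)
        el <- stats::runif(1, -0.45, 0.45)
        dir <- c(cos(az) * cos(el), sin(az) * cos(el), sin(el))
        dia <- stats::runif(1, diameterRange[1], diameterRange[2])
      }
      dir <- dir / sqrt(sum(dir^2))
      L <- 1.2 * sqrt(sum(extent^2))
      a <- p0 - L / 2 * dir; b <- p0 + L / 2 * dir
      okSep <- all(vapply(lines, function(l)
        lineDist(a, b, l[[1]], l[[2]]) >= minSeparation, TRUE))
      if (okSep) return(list(a = a, b = b, dia = dia))
    }
    NULL
  }
  kinds <- c(rep("penetrating", nPenetrating), rep("capillary", nTubes))
  for (kind in kinds) {
    g <- mk(kind)
    if (is.null(g)) next
    ti <- length(tubes) + 1L
    tubes[[ti]] <- tubeSpec(rbind(g$a, g$b), g$dia, peakIntensity)
    lines[[ti]] <- list(g$a, g$b)
    info[[ti]] <- data.frame(tube = ti, kind = kind, diameter = g$dia,
                             parent = NA_integer_)
  }
  nPrim <- length(tubes)
  if (nBranches > 0 && nPrim > 0) {
    for (bi in seq_len(nBranches)) {
      parent <- sample(nPrim, 1)
      pc <- tubes[[parent]]$centerline
      t0 <- stats::runif(1, 0.35, 0.65)
      base <- pc[1, ] + t0 * (pc[2, ] - pc[1, ])
      pd <- (pc[2, ] - pc[1, ]) / sqrt(sum((pc[2, ] - pc[1, ])^2))
      perp <- perpBasis(pd)
      th <- stats::runif(1, 0, 2 * pi)
      bdir <- 0.7 * pd + 0.7 * (cos(th) * perp[1, ] + sin(th) * perp[2, ])
      bdir <- bdir / sqrt(sum(bdir^2))
      blen <- stats::runif(1, 30, 60)
      dia <- 0.8 * tubes[[parent]]$diameter[1]
      ti <- length(tubes) + 1L
      tubes[[ti]] <- tubeSpec(rbind(base, base + blen * bdir), dia,
                              tubes[[parent]]$peakIntensity)
      info[[ti]] <- data.frame(tube = ti, kind = "branch",
                               diameter = dia, parent = parent)
    }
  }
  list(tubes = tubes, info = do.call(rbind, info))
}

## Bifurcation points (tube endpoints touching another tube's centerline)
## plus endpoints, until at least 10 landmarks.
phantomLandmarks <- function(tubes, tol = 2, minCount = 10) {
  ends <- do.call(rbind, lapply(tubes, function(t)
    rbind(t$centerline[1, ], t$centerline[nrow(t$centerline), ])))
  dense <- lapply(tubes, function(t)
    resamplePolyline(t$centerline, t$diameter, 0.5)$points)
  isBif <- logical(nrow(ends))
  for (i in seq_len(nrow(ends))) {
    ti <- ceiling(i / 2)
    for (j in seq_along(dense)) {
      if (j == ti) next
      if (min(sqrt(rowSums(sweep(dense[[j]], 2, ends[i, ])^2))) <= tol) {
        isBif[i] <- TRUE
        break
      }
    }
  }
  lm <- ends[isBif, , drop = FALSE]
  if (nrow(lm) < minCount)
    lm <- unique(rbind(lm, ends))
  if (nrow(lm) < minCount) {
    mids <- do.call(rbind, lapply(tubes, function(t) {
      rs <- resamplePolyline(t$centerline, t$diameter, 0.5)$points
      rs[ceiling(nrow(rs) / 2), , drop = FALSE]
    }))
    lm <- unique(rbind(lm, mids))
  }
  lm
}
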
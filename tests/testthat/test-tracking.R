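# Medial-atom tracking: seeding, boundary model, atom fitting, tracing,
# network assembly, hair pruning, diameter recomputation.

test_that("seed selection matches the brute-force local-maximum scan", {
  # single bright centre voxel
  v <- array(0, c(3, 3, 3)); v[2, 2, 2] <- 5
  s <- selectSeeds(ImageVolume(v, ISO), 1)
  expect_equal(as.integer(s[1, c("i", "j", "k")]), c(2L, 2L, 2L))
  expect_equal(nrow(s), 1L)
  # random volumes, including ties from quantization
  for (sd in 1:8) {
    set.seed(sd)
    v <- array(round(runif(20^3), 2), c(20, 20, 20))
    vol <- ImageVolume(v, ISO)
    thr <- as.numeric(quantile(v, 0.9))
    got <- selectSeeds(vol, thr)
    want <- bruteForceSeeds(v, thr)
    expect_equal(as.matrix(got[, c("i", "j", "k")]), want,
                 ignore_attr = TRUE)
  }
})

test_that("seeds on a noiseless tube lie within one voxel of the axis", {
  tv <- tubeVolume(6, ang = 0.35)
  s <- selectSeeds(tv$volume, 20)
  expect_gt(nrow(s), 5)
  d <- sqrt(pointSegmentDistanceTest(as.matrix(s[, c("x", "y", "z")]),
                                     tv$cl[1, ], tv$cl[2, ]))
  expect_lte(max(d), 1.5 * sqrt(3))
})

test_that("boundary ellipse combines vessel and PSF widths", {
  psf <- PSFModel(lateralFwhm = 3, axialFwhm0 = 3, axialSlope = 0)
  # isotropic PSF: circle of FWHM sqrt(d^2 + p^2)
  be <- boundaryEllipse(radius = 2, tangent = c(0, 0, 1), depth = 100,
                        psf = psf)
  expect_equal(be$fwhm, rep(sqrt(4^2 + 3^2), 2), tolerance = 1e-9)
  # horizontal tube at depth with anisotropic PSF
  psf2 <- PSFModel(lateralFwhm = 1.0, axialFwhm0 = 3.4,
                   axialSlope = 0.0041)
  be2 <- boundaryEllipse(2, c(1, 0, 0), 1000, psf2)
  expect_equal(be2$fwhm, c(sqrt(17), sqrt(72.25)), tolerance = 1e-8)
  # half-max contour radii relate to the sigma contour by sqrt(2 ln 2)
  be2s <- boundaryEllipse(2, c(1, 0, 0), 1000, psf2, contour = "sigma")
  expect_equal(be2$contourRadii / be2s$contourRadii,
               rep(sqrt(2 * log(2)), 2), tolerance = 1e-9)
  # zero axial slope: ellipses identical at any depth
  psf0 <- PSFModel(lateralFwhm = 1.0, axialFwhm0 = 3.4, axialSlope = 0)
  expect_equal(boundaryEllipse(3, c(1, 0, 0), 0, psf0)$fwhm,
               boundaryEllipse(3, c(1, 0, 0), 1000, psf0)$fwhm)
})

test_that("atom metric peaks at the true radius and vanishes in
           background", {
  tv <- tubeVolume(6, depth = 300)
  psf <- psfTracking()
  atomAt <- function(r) medialAtom(tv$center, r, tv$dir)
  m0 <- atomMetric(tv$volume, atomAt(3), psf)$total
  for (f in c(0.7, 0.85, 1.15, 1.3))
    expect_lt(atomMetric(tv$volume, atomAt(3 * f), psf)$total, m0)
  # constant background: zero metric
  bg <- ImageVolume(array(4, c(24, 24, 24)), ISO)
  expect_equal(atomMetric(bg, medialAtom(c(18, 18, 18), 3, c(1, 0, 0)),
                          psf)$total, 0, tolerance = 1e-9)
})

test_that("metric maximization recentres a laterally offset atom", {
  tv <- tubeVolume(6, depth = 300)
  psf <- psfTracking()
  off <- tv$center + c(0, 1.4, 1.4)   # ~2 um off-axis
  a <- fitAtom(tv$volume, medialAtom(off, 3, tv$dir), psf)
  d <- sqrt(pointSegmentDistanceTest(a$position, tv$cl[1, ], tv$cl[2, ]))
  expect_lt(d, 0.5)
})

test_that("atom fitting recovers diameters at depth with the correct
           PSF", {
  psf <- psfTracking()
  a6 <- local({
    tv <- tubeVolume(6, depth = 300)
    fitAtom(tv$volume, medialAtom(tv$center, 2.5, tv$dir), psf)
  })
  expect_equal(2 * a6$radius, 6, tolerance = 0.05)
  a3 <- local({
    tv <- tubeVolume(3, depth = 800)
    fitAtom(tv$volume, medialAtom(tv$center, 2.5, tv$dir), psf)
  })
  expect_equal(2 * a3$radius, 3, tolerance = 0.10)
  # an atom in pure background yields a metric below any sane
  # termination threshold
  tv <- tubeVolume(6, depth = 300)
  thr <- vesseltrace:::metricThreshold(tv$volume, trackerConfig())
  far <- tv$center + c(0, 22, 10)
  aBg <- fitAtom(tv$volume, medialAtom(far, 2.5, tv$dir), psf)
  expect_lt(aBg$metric, thr)
})

test_that("tracing covers a straight tube and ignores redundant seeds", {
  tv <- tubeVolume(6, depth = 100, ang = 0.3, shape = c(64, 64, 30))
  psf <- psfTracking()
  cfg <- trackerConfig()
  res <- traceFromSeed(tv$volume, tv$center, psf, cfg)
  expect_gt(length(res$atoms), 2)
  P <- t(vapply(res$atoms, `[[`, numeric(3), "position"))
  # coverage: fraction of in-volume centerline samples near an atom
  ext <- (dim(voxels(tv$volume)) - 1) * 1.5
  tpts <- seq(0, 1, length.out = 400)
  cl <- sweep(outer(tpts, tv$cl[2, ] - tv$cl[1, ]), 2, tv$cl[1, ], "+")
  inb <- rowSums(cl >= 0 & sweep(cl, 2, ext, "<=")) == 3
  cl <- cl[inb, ]
  nnd <- vapply(seq_len(nrow(cl)), function(i)
    sqrt(min(rowSums(sweep(P, 2, cl[i, ])^2))), 1)
  expect_gte(mean(nnd <= 2.5), 0.95)
  # occupancy: a second seed inside the traced tube yields nothing
  occ <- array(0L, dim(voxels(tv$volume)))
  occ <- vesseltrace:::markOccupancy(occ, tv$volume, res$atoms, 1L)
  res2 <- traceFromSeed(tv$volume, tv$center + 3 * tv$dir, psf, cfg,
                        occupancy = occ)
  expect_null(res2)
})

test_that("a Y junction emits a branch candidate near the true fork", {
  vs <- ISO
  j <- c(36, 36, 24)
  main <- tubeSpec(rbind(c(-10, 36, 24), c(82, 36, 24)), 6, 100)
  bdir <- c(0.3, 0.9, 0.3) / sqrt(sum(c(0.3, 0.9, 0.3)^2))
  branch <- tubeSpec(rbind(j, j + 40 * bdir), 5, 100)
  spec <- phantomSpec(c(49, 49, 33), vs, list(main, branch),
                      surfaceZ = 0)
  vol <- blurXY(suppressWarnings(
    renderVesselPhantom(spec, PSFModel(axialSlope = 0)))$volume, 1.5)
  psf <- psfConstTracking()
  res <- traceFromSeed(vol, c(15, 36, 24), psf, trackerConfig())
  expect_gt(nrow(res$branches), 0)
  dj <- sqrt(rowSums(sweep(as.matrix(res$branches[, c("x", "y", "z")]),
                           2, j)^2))
  expect_lt(min(dj), 3)
})

test_that("three disjoint tubes give three connected components", {
  tubes <- list(
    tubeSpec(rbind(c(-10, 15, 12), c(100, 15, 12)), 6, 100),
    tubeSpec(rbind(c(-10, 45, 30), c(100, 45, 30)), 5, 90),
    tubeSpec(rbind(c(-10, 75, 48), c(100, 75, 48)), 7, 110))
  spec <- phantomSpec(c(61, 61, 41), ISO, tubes)
  vol <- blurXY(suppressWarnings(
    renderVesselPhantom(spec, PSFModel(axialSlope = 0)))$volume, 1.5)
  net <- trackImage(vol, psfConstTracking())
  g <- igraph::graph_from_edgelist(
    matrix(as.character(edgeTable(net)), ncol = 2), directed = FALSE)
  expect_equal(igraph::components(g)$no, 3L)
})

test_that("a tube partially outside the field of view is still traced", {
  # tube enters through a corner and leaves through a face
  tubes <- list(tubeSpec(rbind(c(-30, -30, 18), c(120, 60, 30)), 6, 100))
  spec <- phantomSpec(c(49, 49, 33), ISO, tubes)
  vol <- blurXY(suppressWarnings(
    renderVesselPhantom(spec, PSFModel(axialSlope = 0)))$volume, 1.5)
  net <- trackImage(vol, psfConstTracking())
  expect_gt(nrow(vertexTable(net)), 10)
  d <- sqrt(pointSegmentDistanceTest(
    as.matrix(vertexTable(net)[, c("x", "y", "z")]),
    c(-30, -30, 18), c(120, 60, 30)))
  expect_lt(median(d), 1.5)
})

test_that("tracking is invariant to global intensity rescaling", {
  tv <- tubeVolume(6, depth = 200, ang = 0.7, shape = c(48, 48, 30))
  psf <- psfTracking()
  net1 <- trackImage(tv$volume, psf)
  vol2 <- ImageVolume(voxels(tv$volume) * 40, ISO,
                      volumeOrigin(tv$volume), surfaceZ(tv$volume))
  net2 <- trackImage(vol2, psf)
  A <- as.matrix(vertexTable(net1)[, c("x", "y", "z")])
  B <- as.matrix(vertexTable(net2)[, c("x", "y", "z")])
  nnd <- vapply(seq_len(nrow(A)), function(i)
    sqrt(min(rowSums(sweep(B, 2, A[i, ])^2))), 1)
  expect_lt(max(nnd), 1.5)
})

test_that("hair pruning follows the radius + allowance rule and is
           idempotent", {
  # parent of radius 4 along x; free-end hairs of 10 um and 15 um
  mkNet <- function(hairLen) {
    main <- cbind(seq(0, 60, by = 3), 30, 30)
    n <- nrow(main)
    hair <- cbind(30, 30 + seq(3, hairLen, by = 3), 30)
    nh <- nrow(hair)
    v <- data.frame(id = seq_len(n + nh),
                    x = c(main[, 1], hair[, 1]),
                    y = c(main[, 2], hair[, 2]),
                    z = c(main[, 3], hair[, 3]),
                    radius = c(rep(4, n), rep(1, nh)),
                    signal = 1, depth = 30)
    junction <- which(main[, 1] == 30)
    edges <- rbind(cbind(1:(n - 1), 2:n),
                   c(junction, n + 1),
                   if (nh > 1) cbind(n + 1:(nh - 1), n + 2:nh))
    buildSegments(VesselNetwork(v, edges))
  }
  short <- mkNet(9)    # hair arc length 9 <= 4 + 8
  pruned <- pruneHairs(short, 8)
  expect_equal(nrow(segmentTable(pruned)), 1L)
  long <- mkNet(15)    # 15 > 12: kept
  kept <- pruneHairs(long, 8)
  expect_equal(nrow(segmentTable(kept)), 3L)
  # idempotent; no free ends -> unchanged
  again <- pruneHairs(kept, 8)
  expect_equal(nrow(segmentTable(again)), nrow(segmentTable(kept)))
  expect_equal(nrow(vertexTable(again)), nrow(vertexTable(kept)))
})

test_that("pruning never disconnects junction-to-junction paths and
           monotonically removes edges", {
  for (sd in 1:4) {
    net <- randomTreeNetwork(nJunctions = 8, seed = sd)
    pruned <- pruneHairs(net, 8)
    expect_lte(nrow(edgeTable(pruned)), nrow(edgeTable(net)))
    # every surviving pair of junction vertices that was connected
    # before is still connected
    g0 <- igraph::graph_from_edgelist(
      matrix(as.character(edgeTable(net)), ncol = 2), FALSE)
    g1 <- igraph::graph_from_edgelist(
      matrix(as.character(edgeTable(pruned)), ncol = 2), FALSE)
    deg1 <- vertexDegrees(pruned)
    juncs <- names(deg1)[deg1 >= 3]
    if (length(juncs) >= 2) {
      for (q in 2:length(juncs)) {
        reach0 <- !is.infinite(igraph::distances(g0, juncs[1],
                                                 juncs[q]))
        reach1 <- !is.infinite(igraph::distances(g1, juncs[1],
                                                 juncs[q]))
        expect_equal(reach1, reach0, ignore_attr = TRUE)
      }
    }
  }
})

test_that("diameter recomputation is self-consistent and reproduces the
           constant-PSF bias", {
  psfVary <- psfTracking()
  psfConst <- psfConstTracking()
  tv <- tubeVolume(3, depth = 900, ang = 0.45, shape = c(48, 48, 30))
  net <- trackImage(tv$volume, psfVary)
  expect_gt(nrow(vertexTable(net)), 5)
  # same PSF: radii unchanged within optimizer tolerance
  same <- recomputeDiameters(net, tv$volume, psfVary)
  expect_equal(vertexTable(same)$radius, vertexTable(net)$radius,
               tolerance = 0.02)
  # constant-PSF assumption inflates radii at depth
  con <- recomputeDiameters(net, tv$volume, psfConst)
  ok <- is.finite(vertexTable(con)$radius)
  expect_true(all(vertexTable(con)$radius[ok] >
                    vertexTable(net)$radius[ok] - 1e-6))
  implPct <- 100 * (median(vertexTable(con)$radius[ok]) -
                      median(vertexTable(net)$radius[ok])) /
    median(vertexTable(net)$radius[ok])
  # continuous-domain oracle of the same estimator: analytic Gaussian
  # intensities, exact gradients, no imaging or interpolation
  oraclePct <- local({
    sigd <- fwhmToSigma(3)
    lamY <- fwhmToSigma(lateralFwhm(psfVary))^2
    lamZt <- fwhmToSigma(axialFwhmAtDepth(psfVary, 900))^2
    lamZ0 <- fwhmToSigma(3.4)^2
    phi <- 2 * pi * (0:7) / 8
    u <- cbind(cos(phi), sin(phi))
    metric <- function(sr, lamZmodel) {
      C <- diag(c(sr^2 + lamY, sr^2 + lamZmodel))
      SI <- diag(c(sigd^2 + lamY, sigd^2 + lamZt))
      tt <- 1 / sqrt(rowSums((u %*% solve(C)) * u))
      sRay <- 1 / sqrt(rowSums((u %*% solve(SI)) * u))
      sum(tt / sRay^2 * exp(-tt^2 / (2 * sRay^2)))
    }
    rC <- optimize(function(s) metric(s, lamZ0),
                   c(0.3, 6), maximum = TRUE, tol = 1e-5)$maximum
    rV <- optimize(function(s) metric(s, lamZt),
                   c(0.3, 6), maximum = TRUE, tol = 1e-5)$maximum
    100 * (rC - rV) / rV
  })
  expect_lt(abs(implPct - oraclePct), 3)
  # at depth 0 the two PSF models coincide: identical radii
  tv0 <- tubeVolume(4, depth = 0, ang = 0.45, shape = c(48, 48, 30))
  net0 <- trackImage(tv0$volume, psfVary)
  a <- recomputeDiameters(net0, tv0$volume, psfVary)
  b <- recomputeDiameters(net0, tv0$volume, psfConst)
  expect_equal(vertexTable(a)$radius, vertexTable(b)$radius,
               tolerance = 1e-6)
})
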
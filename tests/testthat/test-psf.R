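# Depth-varying PSF model, refractive scaling, marginalization, and
# bead-stack calibration.

test_that("axial FWHM follows the linear depth model", {
  m <- PSFModel(lateralFwhm = 1, axialFwhm0 = 3.4, axialSlope = 0.0041)
  expect_equal(axialFwhmAtDepth(m, 0), 3.4)
  expect_equal(axialFwhmAtDepth(m, 1000), 7.5)
  expect_equal(axialFwhmAtDepth(m, 500), 5.45)
  expect_error(axialFwhmAtDepth(m, -1), "depth")
})

test_that("refractive axial scale factor is the index ratio", {
  expect_equal(round(axialScaleFactor(RefractiveScaling(1.49, 1.33)), 2),
               1.12)
  expect_equal(axialScaleFactor(RefractiveScaling(1.33, 1.33)), 1.0)
  expect_equal(axialScaleFactor(RefractiveScaling(1.52, 1.33)),
               1.52 / 1.33, tolerance = 1e-12)
  expect_error(RefractiveScaling(0.9, 1.33), "exceed 1")
})

test_that("scale factor is monotone increasing in the agent index", {
  fs <- vapply(seq(1.34, 1.6, by = 0.02), function(n)
    axialScaleFactor(RefractiveScaling(n, 1.33)), 1)
  expect_true(all(diff(fs) > 0))
})

test_that("marginal PSF covariance matches axis-aligned expectations", {
  m <- PSFModel(lateralFwhm = 1.0, axialFwhm0 = 3.4, axialSlope = 0.0041)
  # tangent along the optical axis: isotropic lateral marginal
  mp <- marginalPsfCovariance(m, 0, c(0, 0, 1))
  sl <- fwhmToSigma(1.0)
  expect_equal(mp$covariance, sl^2 * diag(2), tolerance = 1e-10)
  # tangent along x at depth 1000: eigen-FWHMs are lateral and axial
  mp2 <- marginalPsfCovariance(m, 1000, c(1, 0, 0))
  expect_equal(mp2$fwhm, c(1.0, 7.5), tolerance = 1e-8)
  expect_error(marginalPsfCovariance(m, 0, c(0, 0, 0)), "tangent")
})

test_that("oblique marginal matches brute-force numerical marginalization", {
  m <- PSFModel(lateralFwhm = 1.0, axialFwhm0 = 3.4, axialSlope = 0.0041)
  depth <- 1000
  tangent <- c(1, 0, 1) / sqrt(2)
  mp <- marginalPsfCovariance(m, depth, tangent)
  # sample the 3D Gaussian on a grid, project onto the perpendicular
  # plane, and measure the covariance of the projected density
  sl <- fwhmToSigma(1.0); sz <- fwhmToSigma(7.5)
  g <- seq(-12, 12, by = 0.25)
  gr <- expand.grid(x = g, y = g, z = g)
  w <- exp(-0.5 * (gr$x^2 / sl^2 + gr$y^2 / sl^2 + gr$z^2 / sz^2))
  E <- mp$basis
  u <- as.matrix(gr) %*% t(E)
  w <- w / sum(w)
  mu <- colSums(u * w)
  uc <- sweep(u, 2, mu)
  Cnum <- t(uc) %*% (uc * w)
  evA <- sort(eigen(mp$covariance, symmetric = TRUE)$values)
  evN <- sort(eigen(Cnum, symmetric = TRUE)$values)
  expect_equal(sqrt(evA), sqrt(evN), tolerance = 0.01)
})

test_that("marginal covariance is SPD with eigen-FWHMs between bounds", {
  m <- PSFModel(lateralFwhm = 1.2, axialFwhm0 = 3.4, axialSlope = 0.0041)
  set.seed(4)
  for (q in 1:25) {
    t <- rnorm(3); t <- t / sqrt(sum(t^2))
    depth <- runif(1, 0, 1000)
    mp <- marginalPsfCovariance(m, depth, t)
    ev <- eigen(mp$covariance, symmetric = TRUE)$values
    expect_true(all(ev > 0))
    f <- sigmaToFwhm(sqrt(ev))
    expect_true(all(f >= 1.2 - 1e-9))
    expect_true(all(f <= axialFwhmAtDepth(m, depth) + 1e-9))
  }
})

test_that("bead profile fit recovers the quadrature-combined FWHM", {
  psf <- PSFModel(lateralFwhm = 1.0, axialFwhm0 = 3.4,
                  axialSlope = 0.0041)
  spec <- beadPhantomSpec(3, beadDiameter = 0.5, depthRange = c(30, 950),
                          psf = psf, volumeShape = c(40, 40, 680),
                          minSeparation = 60, seed = 2)
  rb <- renderBeadPhantom(spec)
  vol <- blurXY(rb$volume, 1.5)
  for (b in seq_len(nrow(rb$beads))) {
    ctr <- as.numeric(rb$beads[b, c("x", "y", "z")])
    depth <- rb$beads$depth[b]
    fz <- fitBeadFwhm(vol, ctr, axis = "z")
    expF <- sqrt(0.5^2 + axialFwhmAtDepth(psf, depth)^2)
    expect_equal(fz$fwhm, expF, tolerance = 0.02 * expF)
    fx <- fitBeadFwhm(vol, ctr, axis = "x")
    ## lateral widths sit near half a voxel at 1.5 um sampling, so the
    ## discrete profile underestimates the continuous quadrature sum by
    ## a phase-dependent few percent; tolerance reflects that
    expFx <- sqrt(0.5^2 + 1.0^2 + 1.5^2)
    expect_equal(fx$fwhm, expFx, tolerance = 0.12)
  }
})

test_that("bead fit errors on flat background", {
  vol <- ImageVolume(array(3, c(20, 20, 20)), ISO)
  expect_error(fitBeadFwhm(vol, c(15, 15, 15), axis = "z"))
})

test_that("profile of an exact discrete Gaussian recovers its sigma", {
  s <- 2.3
  ax <- (0:39) * 1.5
  g <- exp(-(ax - 30)^2 / (2 * s^2))
  v <- array(0, c(40, 9, 9))
  v[, 5, 5] <- g
  # make the bead 3D so centre-of-mass refinement stays put
  for (dj in -2:2) for (dk in -2:2)
    v[, 5 + dj, 5 + dk] <- g * exp(-((dj * 1.5)^2 + (dk * 1.5)^2) /
                                     (2 * s^2))
  vol <- ImageVolume(v, ISO)
  f <- fitBeadFwhm(vol, c(30, 6 * 1.5, 6 * 1.5), axis = "x",
                   halfWidth = 15)
  expect_equal(f$sigma, s, tolerance = 1e-4)
})

test_that("depth calibration recovers the generating axial model", {
  psf <- PSFModel(lateralFwhm = 1.0, axialFwhm0 = 3.4,
                  axialSlope = 0.0041)
  spec <- beadPhantomSpec(40, beadDiameter = 0.5,
                          depthRange = c(10, 990), psf = psf,
                          volumeShape = c(72, 72, 680),
                          minSeparation = 25, seed = 7)
  rb <- renderBeadPhantom(spec)
  vol <- blurXY(rb$volume, 1.5)
  fits <- do.call(rbind, lapply(seq_len(nrow(rb$beads)), function(b) {
    ctr <- as.numeric(rb$beads[b, c("x", "y", "z")])
    data.frame(depth = rb$beads$depth[b],
               fwhm_x = fitBeadFwhm(vol, ctr, "x")$fwhm,
               fwhm_z = fitBeadFwhm(vol, ctr, "z")$fwhm)
  }))
  cal <- calibratePsfDepthModel(fits)
  expect_equal(axialFwhm0(cal$model), 3.4, tolerance = 0.05)
  expect_equal(axialSlope(cal$model), 0.0041, tolerance = 0.05)
  # lateral slope not significant; lateral mean near the blurred width
  expect_gt(cal$lateralSlopeP, 0.05)
  expect_equal(cal$lateralMean, sqrt(0.5^2 + 1^2 + 1.5^2),
               tolerance = 0.12)
})

test_that("calibration input validation", {
  df <- data.frame(depth = c(100, 100, 100, 100, 100),
                   fwhm_x = 2, fwhm_z = 4)
  expect_error(calibratePsfDepthModel(df), "distinct depths")
  expect_error(calibratePsfDepthModel(df[1:3, ]), "at least 5")
})

test_that("constant-axial-PSF beads yield a slope consistent with 0", {
  psf <- PSFModel(lateralFwhm = 1.0, axialFwhm0 = 3.4, axialSlope = 0)
  hits <- 0L
  for (sd in 1:10) {
    spec <- beadPhantomSpec(12, beadDiameter = 0.5,
                            depthRange = c(10, 590), psf = psf,
                            volumeShape = c(48, 48, 410),
                            minSeparation = 30, peakIntensity = 100,
                            noise = list(type = "gaussian", sd = 0.02),
                            seed = sd)
    rb <- renderBeadPhantom(spec)
    vol <- blurXY(rb$volume, 1.5)
    fits <- do.call(rbind, lapply(seq_len(nrow(rb$beads)), function(b) {
      ctr <- as.numeric(rb$beads[b, c("x", "y", "z")])
      data.frame(depth = rb$beads$depth[b],
                 fwhm_x = fitBeadFwhm(vol, ctr, "x")$fwhm,
                 fwhm_z = fitBeadFwhm(vol, ctr, "z")$fwhm)
    }))
    cal <- calibratePsfDepthModel(fits)
    zp <- summary(cal$axialFit)$coefficients["depth", "Pr(>|t|)"]
    if (zp > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("PSF model YAML round-trips", {
  m <- PSFModel(1.7, 3.4, 0.0041)
  path <- tempfile(fileext = ".yaml")
  writePSFModel(m, path, RefractiveScaling(1.49, 1.33))
  back <- readPSFModel(path)
  expect_equal(lateralFwhm(back$model), 1.7)
  expect_equal(axialFwhm0(back$model), 3.4)
  expect_equal(axialSlope(back$model), 0.0041)
  expect_equal(axialScaleFactor(back$refractive), 1.49 / 1.33)
})
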
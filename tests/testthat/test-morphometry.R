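# Morphometry: penetrating-vessel tracing, capillary labels, perfusion
# CNR, shadow labels, normalization, attenuation fits, matched ratios.

test_that("penetrating trace follows the smallest angle to the normal", {
  # straight vertical path: the whole path is traversed
  p <- pathNetwork(cbind(50, 50, seq(0, 80, by = 10)))
  tr <- tracePenetratingVessel(p, markerVertex = 1)
  expect_equal(tr$segments, 1L)
  expect_true(all(segmentTable(tr$network)$class_label == "penetrating"))
  # junction with 10 deg and 60 deg candidates: 10 deg wins
  mk <- function(angDeg, from, n = 5) {
    a <- angDeg * pi / 180
    t(sapply(seq_len(n), function(i)
      from + i * 10 * c(sin(a), 0, cos(a))))
  }
  stem <- cbind(50, 50, seq(0, 30, by = 10))
  j <- c(50, 50, 30)
  b10 <- mk(10, j); b60 <- mk(60, j)
  coords <- rbind(stem, b10, b60)
  n1 <- nrow(stem); n2 <- nrow(b10)
  edges <- rbind(cbind(1:(n1 - 1), 2:n1),
                 rbind(c(n1, n1 + 1),
                       cbind(n1 + 1:(n2 - 1), n1 + 2:n2)),
                 rbind(c(n1, n1 + n2 + 1),
                       cbind(n1 + n2 + 1:(n2 - 1), n1 + n2 + 2:n2)))
  net <- pathNetwork(coords, edges = edges)
  tr <- tracePenetratingVessel(net, markerVertex = 1)
  lastSeg <- tr$segments[length(tr$segments)]
  lastIds <- segmentPaths(tr$network)[[lastSeg]]
  # the traced path ends in the 10-degree branch
  expect_true(any(lastIds %in% (n1 + 1):(n1 + n2)))
  expect_false(any(lastIds %in% (n1 + n2 + 2):(n1 + 2 * n2)))
  expect_error(tracePenetratingVessel(net, markerVertex = 999), "marker")
})

test_that("penetrating trace equals the brute-force greedy rule on
           random trees", {
  for (sd in 1:6) {
    net <- randomTreeNetwork(nJunctions = sample(4:12, 1), seed = sd)
    marker <- vertexTable(net)$id[1]
    tr <- tracePenetratingVessel(net, marker)
    expect_equal(tr$segments, greedyPenetratingOracle(net, marker))
  }
})

test_that("capillary classification respects the 8 um rule and
           penetrating precedence", {
  p <- pathNetwork(cbind(50, 50, seq(0, 60, by = 10)), radius = 2.5)
  lab <- classifyCapillaries(p)
  expect_equal(segmentTable(lab)$class_label, "capillary")
  big <- pathNetwork(cbind(0, 0, seq(0, 60, by = 10)), radius = 5)
  expect_equal(segmentTable(classifyCapillaries(big))$class_label,
               "unset")
  pen <- tracePenetratingVessel(p, markerVertex = 1)$network
  both <- classifyCapillaries(pen)
  expect_equal(segmentTable(both)$class_label, "penetrating")
})

test_that("perfusion CNR flags exactly the unrendered tubes", {
  lay <- randomTubeLayout(nTubes = 20, extent = c(120, 120, 90),
                          minSeparation = 14, seed = 31)
  tubes <- lay$tubes
  unper <- c(3, 11)
  for (ti in unper) tubes[[ti]]$peakIntensity <- 0.0
  spec <- phantomSpec(c(81, 81, 61), ISO, tubes, backgroundLevel = 1,
                      noise = list(type = "gaussian", sd = 0.5),
                      seed = 4)
  r <- suppressWarnings(
    renderVesselPhantom(spec, PSFModel(axialSlope = 0)))
  truth <- r$truth
  # clip truth to the volume so every vertex samples real voxels
  vt <- vertexTable(truth)
  ext <- (dim(voxels(r$volume)) - 1) * 1.5
  keep <- vt$x >= 0 & vt$x <= ext[1] & vt$y >= 0 & vt$y <= ext[2] &
    vt$z >= 0 & vt$z <= ext[3]
  ids <- vt$id[keep]
  E <- edgeTable(truth)
  E <- E[E[, 1] %in% ids & E[, 2] %in% ids, , drop = FALSE]
  net <- buildSegments(VesselNetwork(vt[keep, ], E))
  pr <- perfusionCNR(net, r$volume, backgroundThreshold = 5)
  seg <- segmentTable(pr$network)
  segTube <- vapply(segmentPaths(pr$network), function(p)
    vt$segment_id[match(p[2], vt$id)], 1L)
  expect_equal(sort(unique(segTube[seg$unperfused])), unper)
  expect_equal(pr$perfusedFraction,
               1 - length(unper) / nrow(seg))
  expect_error(perfusionCNR(net, r$volume, backgroundThreshold = -1),
               "background")
})

test_that("CNR is zero at background-level signal and flags are
           invariant to affine intensity rescaling", {
  lay <- randomTubeLayout(nTubes = 8, extent = c(90, 90, 60),
                          minSeparation = 14, seed = 5)
  tubes <- lay$tubes
  tubes[[2]]$peakIntensity <- 0
  spec <- phantomSpec(c(61, 61, 41), ISO, tubes, backgroundLevel = 2,
                      noise = list(type = "gaussian", sd = 0.4),
                      seed = 9)
  r <- suppressWarnings(
    renderVesselPhantom(spec, PSFModel(axialSlope = 0)))
  vt <- vertexTable(r$truth)
  ext <- (dim(voxels(r$volume)) - 1) * 1.5
  keep <- vt$x >= 0 & vt$x <= ext[1] & vt$y >= 0 & vt$y <= ext[2] &
    vt$z >= 0 & vt$z <= ext[3]
  E <- edgeTable(r$truth)
  E <- E[E[, 1] %in% vt$id[keep] & E[, 2] %in% vt$id[keep], ,
         drop = FALSE]
  net <- buildSegments(VesselNetwork(vt[keep, ], E))
  p1 <- perfusionCNR(net, r$volume, backgroundThreshold = 6)
  # affine rescale of volume + consistently transformed threshold
  v2 <- ImageVolume(voxels(r$volume) * 3 + 10, ISO)
  p2 <- perfusionCNR(net, v2, backgroundThreshold = 6 * 3 + 10)
  expect_equal(segmentTable(p1$network)$unperfused,
               segmentTable(p2$network)$unperfused)
  expect_equal(vertexTable(p1$network)$cnr,
               vertexTable(p2$network)$cnr, tolerance = 1e-9)
  # an unperfused tube's vertices sit at background: CNR near 0
  un <- segmentTable(p1$network)$unperfused
  cnrUn <- vertexTable(p1$network)$cnr[
    vertexTable(p1$network)$id %in%
      unlist(segmentPaths(p1$network)[un])]
  expect_lt(stats::median(abs(cnrUn)), 1.5)
})

test_that("shadow labels follow the projected pial mask", {
  # one large shallow (pial) tube along x; capillaries below and beside
  pial <- tubeSpec(rbind(c(-10, 45, 15), c(130, 45, 15)), 14, 100)
  below <- tubeSpec(rbind(c(-10, 45, 60), c(130, 45, 60)), 4, 80)
  beside <- tubeSpec(rbind(c(-10, 8, 60), c(130, 8, 60)), 4, 80)
  net <- suppressWarnings(renderVesselPhantom(
    phantomSpec(c(81, 61, 61), ISO, list(pial, below, beside)),
    PSFModel(axialSlope = 0)))$truth
  net <- buildSegments(net)
  msk <- pialMask(net)
  expect_gt(nrow(msk), 0)
  out <- classifyShadowed(net, msk)
  vt <- vertexTable(out)
  expect_true(all(vt$shadowed[vt$segment_id == 2], na.rm = TRUE))
  expect_false(any(vt$shadowed[vt$segment_id == 3], na.rm = TRUE))
  seg <- segmentTable(out)
  expect_true(seg$shadowed[2]); expect_false(seg$shadowed[3])
})

test_that("signal normalization maps large-vessel mean to exactly 1", {
  coordsA <- cbind(seq(0, 40, 10), 0, 10)
  coordsB <- cbind(seq(0, 40, 10), 20, 10)
  coordsC <- cbind(seq(0, 40, 10), 40, 10)
  v <- rbind(
    data.frame(id = 1:5, x = coordsA[, 1], y = coordsA[, 2],
               z = coordsA[, 3], radius = 6, signal = 100),
    data.frame(id = 6:10, x = coordsB[, 1], y = coordsB[, 2],
               z = coordsB[, 3], radius = 7, signal = 100),
    data.frame(id = 11:15, x = coordsC[, 1], y = coordsC[, 2],
               z = coordsC[, 3], radius = 2, signal = 50))
  edges <- rbind(cbind(1:4, 2:5), cbind(6:9, 7:10), cbind(11:14, 12:15))
  net <- buildSegments(VesselNetwork(v, edges))
  out <- normalizeSignal(net)
  seg <- segmentTable(out)
  expect_equal(seg$norm_signal[seg$diameter > 10], c(1, 1))
  expect_equal(seg$norm_signal[seg$diameter <= 10], 0.5)
  small <- buildSegments(VesselNetwork(v[11:15, ],
                                       cbind(11:14, 12:15)))
  expect_error(normalizeSignal(small), "normalization diameter")
})

test_that("attenuation fit is exact on noiseless exponentials and
           warns on constant signal", {
  depths <- seq(20, 400, length.out = 25)
  df <- data.frame(depth = depths, signal = exp(-2 * depths / 200))
  fit <- fitAttenuationLength(df, window = c(0, 420))
  expect_equal(fit$attenuationLength, 200, tolerance = 1e-4)
  # single-exponent convention halves the length
  fit1 <- fitAttenuationLength(df, window = c(0, 420),
                               convention = "single")
  expect_equal(fit1$attenuationLength, 100, tolerance = 1e-4)
  cst <- data.frame(depth = depths, signal = 1)
  expect_warning(f2 <- fitAttenuationLength(cst, window = c(0, 420)),
                 "infinite")
  expect_equal(f2$attenuationLength, Inf)
  expect_error(fitAttenuationLength(df[1:5, ], window = c(0, 420)),
               "at least 10")
})

test_that("attenuation estimate is unbiased over noisy replicates", {
  depths <- seq(20, 400, length.out = 30)
  set.seed(123)
  ells <- replicate(200, {
    sig <- exp(-2 * depths / 171) * exp(rnorm(30, 0, 0.1))
    fitAttenuationLength(data.frame(depth = depths, signal = sig),
                         window = c(0, 420))$attenuationLength
  })
  expect_equal(mean(ells), 171, tolerance = 0.02)
})

test_that("matched diameter comparison recovers constructed ratios", {
  net <- randomTreeNetwork(nJunctions = 6, seed = 13)
  netEx <- net
  vex <- vertexTable(netEx)
  vex$radius <- vex$radius * 0.8
  netEx@vertices <- vex
  corr <- data.frame(id_a = vertexTable(net)$id,
                     id_b = vertexTable(net)$id)
  cmp <- compareDiameters(corr, net, netEx)
  expect_equal(cmp$table$ratio, rep(0.8, nrow(cmp$table)),
               tolerance = 1e-9)
  # identical networks give ratio 1 and no unmatched segments
  cmp1 <- compareDiameters(corr, net, net)
  expect_true(all(abs(cmp1$table$ratio - 1) < 1e-12))
  expect_length(cmp1$unmatchedSegments, 0)
  # dropping one segment's vertices lists it as unmatched
  seg1 <- segmentPaths(net)[[1]]
  corr2 <- corr[!corr$id_a %in% seg1, ]
  cmp2 <- compareDiameters(corr2, net, netEx)
  expect_true(1 %in% cmp2$unmatchedSegments)
  expect_error(compareDiameters(corr[0, ], net, netEx), "empty")
})
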
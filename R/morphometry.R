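# Network morphometry: penetrating-vessel tracing, capillary
# classification, perfusion CNR, shadow labeling, signal normalization,
# attenuation-length fits, matched diameter comparison.

#' Morphometry configuration
#'
#' @param capillaryDiameterMax Capillary upper diameter bound, um (a
#'   capillary is a non-penetrating segment below this diameter).
#' @param normalizationDiameterMin Segments above this diameter define
#'   the signal normalization reference (their mean signal maps to 1).
#' @param unperfusedVertexFraction A segment is unperfused when more than
#'   this fraction of its vertices have near-zero CNR.
#' @param nearZeroCnr CNR below this value counts as "approaching zero".
#' @param pialDepthMax,pialDiameterMin Segments shallower than
#'   `pialDepthMax` (um) and wider than `pialDiameterMin` (um) form the
#'   pial mask used for shadow labeling.
#' @param surfaceNormal Unit 3-vector of the cortical surface normal
#'   (pointing into the tissue).
#' @return A validated `MorphometryConfig` list.
#' @export
morphometryConfig <- function(capillaryDiameterMax = 8,
                              normalizationDiameterMin = 10,
                              unperfusedVertexFraction = 0.5,
                              nearZeroCnr = 1.0,
                              pialDepthMax = 50, pialDiameterMin = 10,
                              surfaceNormal = c(0, 0, 1)) {
  stopifnot(capillaryDiameterMax > 0, normalizationDiameterMin > 0,
            unperfusedVertexFraction > 0, unperfusedVertexFraction < 1,
            nearZeroCnr > 0, pialDepthMax > 0, pialDiameterMin > 0)
  structure(list(capillaryDiameterMax = capillaryDiameterMax,
                 normalizationDiameterMin = normalizationDiameterMin,
                 unperfusedVertexFraction = unperfusedVertexFraction,
                 nearZeroCnr = nearZeroCnr, pialDepthMax = pialDepthMax,
                 pialDiameterMin = pialDiameterMin,
                 surfaceNormal = surfaceNormal /
                   sqrt(sum(surfaceNormal^2))),
            class = "MorphometryConfig")
}

segMeanDepth <- function(network) {
  vapply(network@segmentPaths, function(p) {
    ix <- match(p, network@vertices$id)
    mean(network@vertices$depth[ix])
  }, 1)
}

#' Trace a penetrating vessel downward from a marker
#'
#' Starting at a marker vertex near the cortical surface, the trace
#' follows, at every junction, the outgoing segment whose direction
#' (oriented away from the junction) makes the smallest angle with the
#' cortical surface normal, and stops at a free end with no vessel below
#' it. All traversed segments are labeled `"penetrating"`.
#'
#' @param network A [VesselNetwork-class] with segments built.
#' @param markerVertex Vertex id on (or nearest to) the penetrating
#'   vessel near the surface.
#' @param surfaceNormal Unit 3-vector pointing into the tissue.
#' @return List with `segments` (ordered segment ids) and `network`
#'   (segments relabeled).
#' @export
tracePenetratingVessel <- function(network, markerVertex,
                                   surfaceNormal = c(0, 0, 1)) {
  if (!markerVertex %in% network@vertices$id)
    stop("marker vertex is not on the network")
  if (!length(network@segmentPaths)) network <- buildSegments(network)
  nrm <- surfaceNormal / sqrt(sum(surfaceNormal^2))
  paths <- network@segmentPaths
  verts <- network@vertices
  idmap <- seq_len(nrow(verts))
  names(idmap) <- as.character(verts$id)
  segsAt <- function(vid) {
    which(vapply(paths, function(p)
      p[1] == vid || p[length(p)] == vid, TRUE))
  }
  segDirFrom <- function(si, vid) {
    p <- paths[[si]]
    if (p[1] == vid) a <- p[1:min(2, length(p))]
    else a <- p[length(p):max(length(p) - 1, 1)]
    P <- as.matrix(verts[idmap[as.character(a)], c("x", "y", "z")])
    d <- P[nrow(P), ] - P[1, ]
    n <- sqrt(sum(d^2))
    if (n < 1e-12) c(0, 0, 0) else d / n
  }
  ## starting segment: the one at/containing the marker whose direction
  ## best aligns with the normal
  startSegs <- which(vapply(paths, function(p) markerVertex %in% p, TRUE))
  if (!length(startSegs)) stop("marker vertex belongs to no segment")
  cur <- markerVertex
  if (length(startSegs) == 1L && !cur %in%
      c(paths[[startSegs]][1],
        paths[[startSegs]][length(paths[[startSegs]])])) {
    ## marker mid-segment: walk from the marker toward the deeper end
    p <- paths[[startSegs]]
    ends <- c(p[1], p[length(p)])
    zz <- verts$z[idmap[as.character(ends)]]
    cur <- ends[which.max(zz)]
    visited <- startSegs
  } else {
    cand <- segsAt(cur)
    if (!length(cand)) cand <- startSegs
    ang <- vapply(cand, function(si) sum(segDirFrom(si, cur) * nrm), 1)
    first <- cand[which.max(ang)]
    p <- paths[[first]]
    cur <- if (p[1] == cur) p[length(p)] else p[1]
    visited <- first
  }
  repeat {
    cand <- setdiff(segsAt(cur), visited)
    if (!length(cand)) break
    ang <- vapply(cand, function(si) sum(segDirFrom(si, cur) * nrm), 1)
    nxt <- cand[which.max(ang)]
    visited <- c(visited, nxt)
    p <- paths[[nxt]]
    cur <- if (p[1] == cur) p[length(p)] else p[1]
  }
  network@segments$class_label[visited] <- "penetrating"
  for (si in visited) {
    ix <- idmap[as.character(paths[[si]])]
    network@vertices$label[ix] <- "penetrating"
  }
  list(segments = visited, network = network)
}

#' Classify capillary segments
#'
#' Every segment not already labeled penetrating (or pial) whose mean
#' diameter (2 x mean vertex radius) is below the capillary bound (8 um)
#' is labeled `"capillary"`.
#'
#' @param network A [VesselNetwork-class] with segments built.
#' @param config A [morphometryConfig()].
#' @return The relabeled network.
#' @export
classifyCapillaries <- function(network, config = morphometryConfig()) {
  if (!length(network@segmentPaths)) network <- buildSegments(network)
  seg <- network@segments
  sel <- seg$class_label %in% c("unset", "other") &
    seg$diameter < config$capillaryDiameterMax
  network@segments$class_label[sel] <- "capillary"
  idmap <- seq_len(nrow(network@vertices))
  names(idmap) <- as.character(network@vertices$id)
  for (si in which(sel)) {
    ix <- idmap[as.character(network@segmentPaths[[si]])]
    lb <- network@vertices$label[ix]
    network@vertices$label[ix][lb == "unset"] <- "capillary"
  }
  network
}

#' Label pial segments
#'
#' Segments shallower than `pialDepthMax` and wider than
#' `pialDiameterMin` are labeled `"pial"`; these form the shadow mask.
#'
#' @inheritParams classifyCapillaries
#' @return The relabeled network.
#' @export
classifyPial <- function(network, config = morphometryConfig()) {
  if (!length(network@segmentPaths)) network <- buildSegments(network)
  md <- segMeanDepth(network)
  sel <- network@segments$class_label == "unset" &
    md < config$pialDepthMax &
    network@segments$diameter > config$pialDiameterMin
  network@segments$class_label[sel] <- "pial"
  network
}

#' Perfusion scoring by contrast-to-noise ratio
#'
#' Background voxels are those below `backgroundThreshold`. Each vertex's
#' CNR is (signal at the vertex - mean background) / sd background, with
#' the signal sampled from the volume at the (registered) vertex
#' position. A segment is unperfused when more than
#' `unperfusedVertexFraction` of its vertices have CNR below
#' `nearZeroCnr`.
#'
#' @param network A [VesselNetwork-class] registered into the volume's
#'   space (segments built).
#' @param volume The [ImageVolume-class] to score against (e.g. the ex
#'   vivo gel image).
#' @param backgroundThreshold Intensity below which voxels count as
#'   background.
#' @param config A [morphometryConfig()].
#' @return List with `network` (vertex `cnr` filled, segment
#'   `unperfused` column added), `perfusedFraction`, `backgroundMean`,
#'   `backgroundSd`.
#' @export
perfusionCNR <- function(network, volume, backgroundThreshold,
                         config = morphometryConfig()) {
  v <- volume@voxels
  bg <- v[v < backgroundThreshold]
  if (!length(bg)) stop("no background voxels below the threshold")
  mu <- mean(bg); sdv <- stats::sd(bg)
  if (!is.finite(sdv) || sdv == 0) sdv <- .Machine$double.eps
  if (!length(network@segmentPaths)) network <- buildSegments(network)
  verts <- network@vertices
  sig <- sampleIntensity(volume, as.matrix(verts[, c("x", "y", "z")]))
  verts$cnr <- (sig - mu) / sdv
  network@vertices <- verts
  idmap <- seq_len(nrow(verts))
  names(idmap) <- as.character(verts$id)
  unperf <- vapply(network@segmentPaths, function(p) {
    cnr <- verts$cnr[idmap[as.character(p)]]
    mean(cnr < config$nearZeroCnr) > config$unperfusedVertexFraction
  }, TRUE)
  network@segments$unperfused <- unperf
  list(network = network,
       perfusedFraction = 1 - mean(unperf),
       backgroundMean = mu, backgroundSd = sdv)
}

#' Build the pial xy shadow mask
#'
#' Disks centred on the vertices of pial segments (depth below
#' `pialDepthMax`, diameter above `pialDiameterMin`), each with the
#' vertex's own radius, projected to the xy plane.
#'
#' @inheritParams classifyCapillaries
#' @return data.frame with x, y, radius of the mask disks.
#' @export
pialMask <- function(network, config = morphometryConfig()) {
  if (!length(network@segmentPaths)) network <- buildSegments(network)
  md <- segMeanDepth(network)
  pial <- which((network@segments$class_label == "pial") |
                  (md < config$pialDepthMax &
                     network@segments$diameter > config$pialDiameterMin))
  ids <- unlist(network@segmentPaths[pial])
  ix <- match(ids, network@vertices$id)
  data.frame(x = network@vertices$x[ix], y = network@vertices$y[ix],
             radius = network@vertices$radius[ix])
}

#' Label shadowed vertices and segments
#'
#' A vertex is shadowed when its (x, y) position falls under the
#' projected pial mask (within a disk radius of a pial vertex); segments
#' are labeled by majority vote of their vertices.
#'
#' @param network A [VesselNetwork-class] with segments built.
#' @param mask data.frame (x, y, radius) from [pialMask()].
#' @return The network with a logical vertex column `shadowed` and
#'   segment column `shadowed`.
#' @export
classifyShadowed <- function(network, mask) {
  if (!length(network@segmentPaths)) network <- buildSegments(network)
  verts <- network@vertices
  if (!nrow(mask)) {
    verts$shadowed <- rep(FALSE, nrow(verts))
  } else {
    M <- as.matrix(mask[, c("x", "y")])
    shadowed <- logical(nrow(verts))
    for (q in seq_len(nrow(verts))) {
      d2 <- (M[, 1] - verts$x[q])^2 + (M[, 2] - verts$y[q])^2
      shadowed[q] <- any(d2 <= mask$radius^2)
    }
    verts$shadowed <- shadowed
  }
  network@vertices <- verts
  idmap <- seq_len(nrow(verts))
  names(idmap) <- as.character(verts$id)
  network@segments$shadowed <-
    vapply(network@segmentPaths, function(p)
      mean(verts$shadowed[idmap[as.character(p)]]) > 0.5, TRUE)
  network
}

#' Normalize segment signals to large vessels
#'
#' The mean of the mean signals of segments wider than
#' `normalizationDiameterMin` (10 um) is assigned the value 1; every
#' segment's signal is expressed relative to it.
#'
#' @param network A [VesselNetwork-class] with segments built.
#' @param config A [morphometryConfig()].
#' @return The network with a segment column `norm_signal`.
#' @export
normalizeSignal <- function(network, config = morphometryConfig()) {
  if (!length(network@segmentPaths)) network <- buildSegments(network)
  seg <- network@segments
  ref <- seg$diameter > config$normalizationDiameterMin
  if (!any(ref)) stop("no segment above the normalization diameter")
  M <- mean(seg$mean_signal[ref])
  if (!is.finite(M) || M <= 0) stop("reference segments have no signal")
  network@segments$norm_signal <- seg$mean_signal / M
  network
}

#' Fit the characteristic attenuation length
#'
#' Ordinary least squares of log signal against depth over the fit
#' window, with detected fluorescence assumed to decay as
#' exp(-2 depth / ell) (two-photon convention: the detected signal falls
#' at twice the excitation attenuation rate), so ell = -2 / slope.
#' The single-exponent convention (ell = -1 / slope) is available for
#' methods quoted in that form.
#'
#' @param signalByDepth data.frame with columns `depth` (um) and
#'   `signal` (normalized).
#' @param window Length-2 depth interval (um) to fit over.
#' @param convention `"two-photon"` (factor 2) or `"single"`.
#' @return List with `attenuationLength` (um), `stderr`, `intercept`,
#'   `slope`, `fit` (lm), `n`.
#' @export
fitAttenuationLength <- function(signalByDepth,
                                 window = range(signalByDepth$depth),
                                 convention = c("two-photon", "single")) {
  convention <- match.arg(convention)
  df <- as.data.frame(signalByDepth)
  df <- df[df$depth >= window[1] & df$depth <= window[2], , drop = FALSE]
  if (any(df$signal <= 0)) {
    warning("dropping non-positive signals in the fit window")
    df <- df[df$signal > 0, , drop = FALSE]
  }
  if (nrow(df) < 10) stop("need at least 10 points spanning the window")
  fit <- stats::lm(log(signal) ~ depth, data = df)
  sl <- stats::coef(fit)[["depth"]]
  se <- suppressWarnings(
    summary(fit)$coefficients["depth", "Std. Error"])
  fac <- if (convention == "two-photon") 2 else 1
  if (sl >= 0) {
    warning("non-negative slope: attenuation length is infinite")
    ell <- Inf; ellSe <- NA_real_
  } else {
    ell <- -fac / sl
    ellSe <- fac * se / sl^2
  }
  list(attenuationLength = unname(ell), stderr = unname(ellSe),
       intercept = unname(stats::coef(fit)[[1]]), slope = unname(sl),
       fit = fit, n = nrow(df))
}

#' Compare matched diameters between two networks
#'
#' For every segment of the first (in vivo) network with matched
#' vertices in the second, computes the ratio of the matched mean
#' diameters (ex/in), carrying the in vivo class label, and summarizes
#' per class.
#'
#' @param correspondence data.frame with columns `id_a` (vertices of
#'   `netIn`) and `id_b` (vertices of `netEx`), e.g. `pairs` from
#'   [matchVertices()].
#' @param netIn,netEx [VesselNetwork-class] objects with segments built;
#'   `netEx` diameters are expected to have been recomputed in `netIn`'s
#'   space.
#' @return List with `table` (per-segment ratios), `summary` (per-class
#'   mean ratio, mean +/- sd diameters, n), `fractionCapillariesLargerInVivo`,
#'   `unmatchedSegments`.
#' @export
compareDiameters <- function(correspondence, netIn, netEx) {
  if (!nrow(correspondence)) stop("empty vertex correspondence")
  if (!length(netIn@segmentPaths)) netIn <- buildSegments(netIn)
  vin <- netIn@vertices
  vex <- netEx@vertices
  rIn <- vin$radius[match(correspondence$id_a, vin$id)]
  rEx <- vex$radius[match(correspondence$id_b, vex$id)]
  rows <- list()
  for (si in seq_along(netIn@segmentPaths)) {
    sel <- which(correspondence$id_a %in% netIn@segmentPaths[[si]] &
                   is.finite(rIn) & is.finite(rEx))
    if (!length(sel)) next
    din <- 2 * mean(rIn[sel]); dex <- 2 * mean(rEx[sel])
    rows[[length(rows) + 1L]] <-
      data.frame(segment_id = si, n_matched = length(sel),
                 diameter_in = din, diameter_ex = dex,
                 ratio = dex / din,
                 class_label = netIn@segments$class_label[si],
                 stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab)) stop("no segment had matched vertices")
  summ <- do.call(rbind, lapply(split(tab, tab$class_label), function(g) {
    data.frame(class_label = g$class_label[1], n = nrow(g),
               mean_ratio = mean(g$ratio),
               mean_diameter_in = mean(g$diameter_in),
               sd_diameter_in = stats::sd(g$diameter_in),
               mean_diameter_ex = mean(g$diameter_ex),
               sd_diameter_ex = stats::sd(g$diameter_ex),
               stringsAsFactors = FALSE)
  }))
  caps <- tab[tab$class_label == "capillary", , drop = FALSE]
  fracLarger <- if (nrow(caps)) mean(caps$ratio < 1) else NA_real_
  matchedSegs <- unique(tab$segment_id)
  allSegs <- netIn@segments$segment_id
  list(table = tab, summary = summ,
       fractionCapillariesLargerInVivo = fracLarger,
       unmatchedSegments = setdiff(allSegs, matchedSegs))
}
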
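# Vessel-graph operations: segment decomposition, thin-plate-spline
# landmark registration, vertex matching, volume warping.

#' Vertex degrees of a network
#'
#' @param network A [VesselNetwork-class].
#' @return Named integer vector (names are vertex ids).
#' @export
vertexDegrees <- function(network) {
  ids <- network@vertices$id
  deg <- integer(length(ids))
  names(deg) <- as.character(ids)
  if (nrow(network@edges)) {
    tb <- table(as.character(as.integer(network@edges)))
    deg[names(tb)] <- as.integer(tb)
  }
  deg
}

#' Partition a network into segments
#'
#' A segment is the part of the network between two bifurcations, between
#' a bifurcation and a free end, or between two free ends: a maximal edge
#' path whose interior vertices have degree 2. Per-segment statistics
#' (arc length, mean radius = mean of member vertex radii, mean signal,
#' diameter = 2 x mean radius) are computed.
#'
#' @param network A [VesselNetwork-class].
#' @return The network with `segmentTable` and `segmentPaths` filled and
#'   vertex `segment_id` assigned (junction vertices belong to several
#'   segments and keep `NA`).
#' @export
buildSegments <- function(network) {
  verts <- network@vertices
  E <- network@edges
  n <- nrow(verts)
  idmap <- seq_len(n)
  names(idmap) <- as.character(verts$id)
  paths <- list()
  if (nrow(E)) {
    adj <- vector("list", n)
    for (e in seq_len(nrow(E))) {
      a <- idmap[as.character(E[e, 1])]
      b <- idmap[as.character(E[e, 2])]
      adj[[a]] <- rbind(adj[[a]], c(e, b))
      adj[[b]] <- rbind(adj[[b]], c(e, a))
    }
    deg <- vapply(adj, function(x) if (is.null(x)) 0L else nrow(x), 1L)
    usedEdge <- logical(nrow(E))
    walk <- function(start, firstEdge, firstNext) {
      path <- c(start)
      usedEdge[firstEdge] <<- TRUE
      cur <- firstNext
      prevEdge <- firstEdge
      repeat {
        path <- c(path, cur)
        if (deg[cur] != 2L) break
        nxt <- adj[[cur]]
        pick <- nxt[nxt[, 1] != prevEdge, , drop = FALSE]
        if (nrow(pick) == 0) break
        if (usedEdge[pick[1, 1]]) break
        usedEdge[pick[1, 1]] <<- TRUE
        prevEdge <- pick[1, 1]
        cur <- pick[1, 2]
      }
      path
    }
    for (v in which(deg != 2L & deg > 0L)) {
      for (row in seq_len(nrow(adj[[v]]))) {
        e <- adj[[v]][row, 1]
        if (usedEdge[e]) next
        paths[[length(paths) + 1L]] <- walk(v, e, adj[[v]][row, 2])
      }
    }
    ## pure cycles (all interior degree 2)
    for (e in which(!usedEdge)) {
      if (usedEdge[e]) next
      a <- idmap[as.character(E[e, 1])]
      paths[[length(paths) + 1L]] <- walk(a, e, idmap[as.character(E[e, 2])])
    }
  }
  segIdOfVertex <- rep(NA_integer_, n)
  stats <- lapply(seq_along(paths), function(si) {
    p <- paths[[si]]
    P <- as.matrix(verts[p, c("x", "y", "z")])
    arc <- if (length(p) > 1) sum(sqrt(rowSums(diff(P)^2))) else 0
    data.frame(segment_id = si, n_vertices = length(p), arc_length = arc,
               mean_radius = mean(verts$radius[p]),
               mean_signal = mean(verts$signal[p]),
               diameter = 2 * mean(verts$radius[p]),
               class_label = "unset", stringsAsFactors = FALSE)
  })
  if (length(paths)) {
    deg <- vertexDegrees(network)
    for (si in seq_along(paths)) {
      p <- paths[[si]]
      inner <- p[deg[as.character(verts$id[p])] <= 2L]
      segIdOfVertex[inner] <- si
    }
  }
  verts$segment_id <- segIdOfVertex
  network@vertices <- verts
  network@segments <- if (length(stats)) do.call(rbind, stats)
  else data.frame(segment_id = integer(), n_vertices = integer(),
                  arc_length = numeric(), mean_radius = numeric(),
                  mean_signal = numeric(), diameter = numeric(),
                  class_label = character(), stringsAsFactors = FALSE)
  network@segmentPaths <- lapply(paths, function(p) verts$id[p])
  network
}

## Segment id of every edge, in edge-table order.
edgeSegmentIds <- function(network) {
  E <- network@edges
  if (!nrow(E)) return(integer())
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  m <- new.env(hash = TRUE)
  for (si in seq_along(network@segmentPaths)) {
    p <- network@segmentPaths[[si]]
    if (length(p) < 2) next
    for (q in seq_len(length(p) - 1L))
      assign(key(p[q], p[q + 1]), si, envir = m)
  }
  vapply(seq_len(nrow(E)), function(e) {
    k <- key(E[e, 1], E[e, 2])
    if (exists(k, m)) get(k, m) else NA_integer_
  }, 1L)
}

#' Fit a 3D interpolating thin-plate spline
#'
#' Solves the standard TPS system with the 3D biharmonic kernel
#' U(r) = r: the transform reproduces every landmark exactly, affine
#' landmark configurations yield (numerically) zero kernel weights, and
#' the weights satisfy the orthogonality side conditions.
#'
#' @param source,target n x 3 matrices of corresponding landmarks (um);
#'   alternatively `source` may be a landmark data.frame with columns
#'   x_in, y_in, z_in, x_ex, y_ex, z_ex (then `target` is ignored and
#'   the transform maps in vivo -> ex vivo).
#' @return A [TPSTransform-class].
#' @export
fitTPS <- function(source, target = NULL) {
  if (is.data.frame(source) && is.null(target)) {
    target <- as.matrix(source[, c("x_ex", "y_ex", "z_ex")])
    source <- as.matrix(source[, c("x_in", "y_in", "z_in")])
  }
  source <- as.matrix(source); target <- as.matrix(target)
  n <- nrow(source)
  if (n < 5) stop("need at least 5 landmark pairs")
  if (nrow(target) != n) stop("source/target landmark counts differ")
  ctr <- sweep(source, 2, colMeans(source))
  sv <- svd(ctr)$d
  if (sv[3] < 1e-8 * max(sv[1], 1))
    stop("landmarks are (near-)coplanar; cannot fit a 3D thin plate spline")
  K <- as.matrix(stats::dist(source))
  P <- cbind(1, source)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  Y <- rbind(target, matrix(0, 4, 3))
  sol <- solve(L, Y)
  methods::new("TPSTransform", source = source, target = target,
               affine = sol[n + 1:4, , drop = FALSE],
               weights = sol[1:n, , drop = FALSE])
}

#' Evaluate a thin-plate-spline transform
#'
#' @param transform A [TPSTransform-class].
#' @param pts n x 3 matrix of points (um).
#' @return n x 3 matrix of mapped points.
#' @export
tpsEval <- function(transform, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  pts <- as.matrix(pts)
  A <- cbind(1, pts) %*% transform@affine
  src <- transform@source
  n <- nrow(src)
  U <- sqrt(pmax(outer(rowSums(pts^2), rep(1, n)) +
                   outer(rep(1, nrow(pts)), rowSums(src^2)) -
                   2 * pts %*% t(src), 0))
  A + U %*% transform@weights
}

#' Bending energy of a TPS transform
#'
#' Zero (numerically) exactly when the landmark correspondence is affine.
#'
#' @param transform A [TPSTransform-class].
#' @return Scalar bending energy.
#' @export
tpsBendingEnergy <- function(transform) {
  K <- as.matrix(stats::dist(transform@source))
  abs(sum(transform@weights * (K %*% transform@weights)))
}

#' Fit the reverse-direction TPS
#'
#' Thin plate splines have no closed-form inverse; the practical inverse
#' is the TPS fitted on swapped landmark pairs, exact at the landmarks
#' and accurate inside their hull for smooth warps.
#'
#' @inheritParams fitTPS
#' @return A [TPSTransform-class] mapping target space back to source
#'   space.
#' @export
inverseTransformFromLandmarks <- function(source, target = NULL) {
  if (is.data.frame(source) && is.null(target)) {
    target <- as.matrix(source[, c("x_ex", "y_ex", "z_ex")])
    source <- as.matrix(source[, c("x_in", "y_in", "z_in")])
  }
  fitTPS(target, source)
}

#' Apply a spatial transform to a network
#'
#' Maps vertex positions; radii, signals and topology are unchanged
#' (radii must be re-measured in the target image with
#' [recomputeDiameters()]); tangents are re-derived from the mapped
#' positions along each segment; depths are recomputed against
#' `surfaceZ`.
#'
#' @param network A [VesselNetwork-class].
#' @param transform A [TPSTransform-class] (or a function mapping an
#'   n x 3 matrix of points).
#' @param surfaceZ Cortical-surface z of the target space, um.
#' @return The transformed network.
#' @export
applyTransform <- function(network, transform, surfaceZ = 0) {
  fn <- if (methods::is(transform, "TPSTransform"))
    function(p) tpsEval(transform, p) else transform
  verts <- network@vertices
  if (!nrow(verts)) return(network)
  P <- fn(as.matrix(verts[, c("x", "y", "z")]))
  verts$x <- P[, 1]; verts$y <- P[, 2]; verts$z <- P[, 3]
  verts$depth <- verts$z - surfaceZ
  network@vertices <- verts
  if (length(network@segmentPaths)) {
    idmap <- seq_len(nrow(verts))
    names(idmap) <- as.character(verts$id)
    for (p in network@segmentPaths) {
      ix <- idmap[as.character(p)]
      tg <- polylineTangents(as.matrix(verts[ix, c("x", "y", "z")]))
      network@vertices$tx[ix] <- tg[, 1]
      network@vertices$ty[ix] <- tg[, 2]
      network@vertices$tz[ix] <- tg[, 3]
    }
    network <- buildSegments(network)
  }
  network
}

#' Match vertices between two networks
#'
#' Mutual-nearest-neighbour pairing within a capture radius of networks
#' already in the same space.
#'
#' @param netA,netB [VesselNetwork-class] objects.
#' @param radius Capture radius, um.
#' @return List with `pairs` (data.frame id_a, id_b, dist),
#'   `unmatchedA`, `unmatchedB` (vertex ids).
#' @export
matchVertices <- function(netA, netB, radius = 3) {
  A <- as.matrix(netA@vertices[, c("x", "y", "z")])
  B <- as.matrix(netB@vertices[, c("x", "y", "z")])
  if (!nrow(A) || !nrow(B))
    return(list(pairs = data.frame(id_a = integer(), id_b = integer(),
                                   dist = numeric()),
                unmatchedA = netA@vertices$id,
                unmatchedB = netB@vertices$id))
  nnOf <- function(X, Y) {
    idx <- integer(nrow(X)); dd <- numeric(nrow(X))
    chunk <- max(1L, floor(2e6 / max(nrow(Y), 1)))
    for (s in seq(1, nrow(X), by = chunk)) {
      e <- min(s + chunk - 1L, nrow(X))
      D2 <- outer(rowSums(X[s:e, , drop = FALSE]^2), rep(1, nrow(Y))) +
        outer(rep(1, e - s + 1L), rowSums(Y^2)) -
        2 * X[s:e, , drop = FALSE] %*% t(Y)
      j <- max.col(-D2)
      idx[s:e] <- j
      dd[s:e] <- sqrt(pmax(D2[cbind(seq_len(e - s + 1L), j)], 0))
    }
    list(idx = idx, dist = dd)
  }
  ab <- nnOf(A, B)
  ba <- nnOf(B, A)
  ia <- seq_len(nrow(A))
  mutual <- ba$idx[ab$idx] == ia & ab$dist <= radius
  pairs <- data.frame(id_a = netA@vertices$id[mutual],
                      id_b = netB@vertices$id[ab$idx[mutual]],
                      dist = ab$dist[mutual])
  list(pairs = pairs,
       unmatchedA = setdiff(netA@vertices$id, pairs$id_a),
       unmatchedB = setdiff(netB@vertices$id, pairs$id_b))
}

#' Warp a volume through a spatial transform
#'
#' Inverse-mapping resampling: every voxel of the output grid is mapped
#' through `transform` (output space -> input space) and the input volume
#' is sampled there trilinearly. Used to carry the ex vivo image into
#' in vivo space before re-measuring diameters.
#'
#' @param volume Input [ImageVolume-class].
#' @param transform A [TPSTransform-class] (or point-mapping function)
#'   from output-space coordinates to input-space coordinates.
#' @param grid An [ImageVolume-class] supplying the output geometry
#'   (defaults to the input's own grid).
#' @return An [ImageVolume-class] on the output grid.
#' @export
warpVolume <- function(volume, transform, grid = volume) {
  fn <- if (methods::is(transform, "TPSTransform"))
    function(p) tpsEval(transform, p) else transform
  d <- dim(grid@voxels)
  ax <- lapply(1:3, function(k)
    grid@origin[k] + (seq_len(d[k]) - 1) * grid@voxelSize[k])
  out <- numeric(prod(d))
  nxy <- d[1] * d[2]
  xy <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]]))
  for (k in seq_len(d[3])) {
    pts <- cbind(xy, ax[[3]][k])
    src <- fn(pts)
    out[(k - 1) * nxy + seq_len(nxy)] <- sampleIntensity(volume, src)
  }
  ImageVolume(array(pmax(out, 0), d), grid@voxelSize, grid@origin,
              grid@surfaceZ,
              provenance = c(volume@provenance,
                             list(list(step = "warpVolume"))))
}
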
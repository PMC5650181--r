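# Independent brute-force oracles shared across test files.

# Exhaustive 6-neighbour local-maximum scan (seed-selection oracle).
bruteForceSeeds <- function(v, thr) {
  d <- dim(v)
  out <- NULL
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (v[i, j, k] <= thr) next
    lin <- i + (j - 1) * d[1] + (k - 1) * d[1] * d[2]
    ok <- TRUE
    for (nb in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                    c(0, 0, -1), c(0, 0, 1))) {
      q <- c(i, j, k) + nb
      if (any(q < 1) || any(q > d)) next
      nv <- v[q[1], q[2], q[3]]
      nlin <- q[1] + (q[2] - 1) * d[1] + (q[3] - 1) * d[1] * d[2]
      if (nv > v[i, j, k] || (nv == v[i, j, k] && nlin < lin)) {
        ok <- FALSE
        break
      }
    }
    if (ok) out <- rbind(out, c(i, j, k))
  }
  out
}

# Independent greedy evaluation of the penetrating-vessel rule.
greedyPenetratingOracle <- function(net, marker, nrm = c(0, 0, 1)) {
  paths <- segmentPaths(net)
  vt <- vertexTable(net)
  pos <- function(id) as.numeric(vt[match(id, vt$id), c("x", "y", "z")])
  dirFrom <- function(p, vid) {
    o <- if (p[1] == vid) pos(p[2]) - pos(p[1])
    else pos(p[length(p) - 1]) - pos(p[length(p)])
    o / sqrt(sum(o^2))
  }
  endsOf <- function(p) c(p[1], p[length(p)])
  segsAt <- function(vid) which(vapply(paths, function(p)
    vid %in% endsOf(p), TRUE))
  cur <- marker; visited <- integer()
  if (!length(segsAt(marker))) {
    containing <- which(vapply(paths, function(p) marker %in% p, TRUE))[1]
    ends <- endsOf(paths[[containing]])
    zz <- vt$z[match(ends, vt$id)]
    cur <- ends[which.max(zz)]
    visited <- containing
  }
  repeat {
    cand <- setdiff(segsAt(cur), visited)
    if (!length(cand)) break
    best <- cand[which.max(vapply(cand, function(si)
      sum(dirFrom(paths[[si]], cur) * nrm), 1))]
    visited <- c(visited, best)
    p <- paths[[best]]
    cur <- if (p[1] == cur) p[length(p)] else p[1]
  }
  visited
}

# Independent maximal degree-2 path decomposition (segment-count oracle).
bruteForceSegmentCount <- function(net) {
  E <- edgeTable(net)
  deg <- table(as.integer(E))
  getDeg <- function(id) {
    d <- deg[as.character(id)]
    ifelse(is.na(d), 0L, as.integer(d))
  }
  used <- rep(FALSE, nrow(E))
  count <- 0L
  incident <- function(id) which(E[, 1] == id | E[, 2] == id)
  other <- function(e, id) if (E[e, 1] == id) E[e, 2] else E[e, 1]
  for (e0 in seq_len(nrow(E))) {
    if (used[e0]) next
    count <- count + 1L
    used[e0] <- TRUE
    for (dirEnd in c(E[e0, 1], E[e0, 2])) {
      cur <- dirEnd
      repeat {
        if (getDeg(cur) != 2L) break
        nxt <- incident(cur)
        nxt <- nxt[!used[nxt]]
        if (!length(nxt)) break
        used[nxt[1]] <- TRUE
        cur <- other(nxt[1], cur)
      }
    }
  }
  count
}
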
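# Plain-format I/O: multi-page TIFF volumes (with a JSON geometry
# sidecar), tab-separated network files, comma-separated landmark
# tables.

#' Write / read an image volume as multi-page TIFF
#'
#' One 16-bit page per z plane. Intensities are scaled into the 16-bit
#' range; the scale, voxel size, origin, cortical-surface z and
#' provenance are stored in a JSON sidecar (`<path>.json`) so that
#' reading restores the volume exactly up to 16-bit quantization.
#'
#' @param volume An [ImageVolume-class].
#' @param path Output TIFF path.
#' @return `readVolumeTIFF` returns an [ImageVolume-class].
#' @export
writeVolumeTIFF <- function(volume, path) {
  v <- volume@voxels
  mx <- max(v)
  scale <- if (mx > 0) mx else 1
  pages <- lapply(seq_len(dim(v)[3]), function(k) t(v[, , k]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(voxel_size_um = volume@voxelSize, origin_um = volume@origin,
               surface_z_um = volume@surfaceZ, intensity_scale = scale,
               provenance = volume@provenance)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeVolumeTIFF
#' @export
readVolumeTIFF <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages))
  v <- array(0, d)
  for (k in seq_along(pages)) v[, , k] <- t(pages[[k]])
  metaPath <- paste0(path, ".json")
  if (file.exists(metaPath)) {
    meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
    prov <- meta$provenance
    if (is.data.frame(prov)) prov <- split(prov, seq_len(nrow(prov)))
    if (is.null(prov)) prov <- list()
    ImageVolume(v * meta$intensity_scale, meta$voxel_size_um,
                meta$origin_um, meta$surface_z_um,
                provenance = as.list(prov))
  } else {
    ImageVolume(v)
  }
}

#' Write / read a vessel network as tab-separated text
#'
#' A single file with a commented header, a `#vertices` block (id, x, y,
#' z, radius, tangent, signal, depth, segment id, cnr, label and any
#' extra columns) and an `#edges` block (id_a, id_b); round-trips
#' losslessly.
#'
#' @param network A [VesselNetwork-class].
#' @param path Output path.
#' @return `readNetworkTSV` returns a [VesselNetwork-class] (segments
#'   are rebuilt if the stored vertices carried segment assignments).
#' @export
writeNetworkTSV <- function(network, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vesseltrace network; coordinates in um",
               "#vertices"), con)
  utils::write.table(network@vertices, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  writeLines("#edges", con)
  e <- as.data.frame(network@edges)
  if (!ncol(e)) e <- data.frame(id_a = integer(), id_b = integer())
  names(e) <- c("id_a", "id_b")
  utils::write.table(e, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeNetworkTSV
#' @export
readNetworkTSV <- function(path) {
  lines <- readLines(path)
  iv <- which(lines == "#vertices")
  ie <- which(lines == "#edges")
  if (!length(iv) || !length(ie)) stop("not a network file: ", path)
  verts <- utils::read.table(text = lines[(iv + 1):(ie - 1)], sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  edges <- if (ie + 1 <= length(lines))
    utils::read.table(text = lines[(ie + 1):length(lines)], sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE)
  else data.frame(id_a = integer(), id_b = integer())
  net <- VesselNetwork(verts, as.matrix(edges))
  hadSegs <- "segment_id" %in% names(verts) && any(!is.na(verts$segment_id))
  if (hadSegs) net <- buildSegments(net)
  net
}

#' Write / read landmark pairs
#'
#' Comma-separated text with one row per pair and columns
#' `x_in,y_in,z_in,x_ex,y_ex,z_ex` (um world coordinates, in vivo
#' first).
#'
#' @param landmarks data.frame with the six coordinate columns.
#' @param path File path.
#' @return `readLandmarks` returns the data.frame.
#' @export
writeLandmarks <- function(landmarks, path) {
  need <- c("x_in", "y_in", "z_in", "x_ex", "y_ex", "z_ex")
  stopifnot(all(need %in% names(landmarks)))
  utils::write.csv(landmarks[, need], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname writeLandmarks
#' @export
readLandmarks <- function(path) {
  lm <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_in", "y_in", "z_in", "x_ex", "y_ex", "z_ex")
  if (!all(need %in% names(lm)))
    stop("landmark file must have columns ", paste(need, collapse = ","))
  lm[, need]
}
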
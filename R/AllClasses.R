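# S4 classes for image volumes, PSF models, vessel networks and
# thin-plate-spline transforms, with constructors and accessors.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' ImageVolume: a 3D scalar image with world geometry
#'
#' Voxel intensities plus the information needed to place every voxel in
#' world coordinates (micrometres): the voxel spacing, the world position
#' of the first voxel centre, and the world z of the cortical surface
#' plane. Depth is measured downward from that plane (surface depth 0).
#'
#' @slot voxels 3D numeric array, `[x, y, z]`.
#' @slot voxelSize Positive numeric length 3, micrometres per voxel.
#' @slot origin World coordinates (um) of voxel `[1, 1, 1]`'s centre.
#' @slot surfaceZ World z (um) of the cortical surface plane.
#' @slot provenance List of processing steps applied so far.
#' @export
setClass("ImageVolume",
         representation(voxels = "array", voxelSize = "numeric",
                        origin = "numeric", surfaceZ = "numeric",
                        provenance = "list"))

setValidity("ImageVolume", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 3L) return("voxels must be a 3D array")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive values (um)")
  if (length(object@origin) != 3L) return("origin must have length 3")
  if (length(object@surfaceZ) != 1L) return("surfaceZ must be a scalar")
  if (anyNA(v) || any(!is.finite(v))) return("intensities must be finite")
  if (min(v) < 0) return("intensities must be non-negative")
  TRUE
})

#' Construct an ImageVolume
#'
#' @param voxels 3D numeric array of intensities, indexed `[x, y, z]`.
#' @param voxelSize Voxel spacing in um, length 1 (isotropic) or 3.
#' @param origin World position (um) of the first voxel centre.
#' @param surfaceZ World z (um) of the cortical surface plane.
#' @param provenance Optional list of processing-step records.
#' @return An [ImageVolume-class] object.
#' @export
ImageVolume <- function(voxels, voxelSize = c(1.5, 1.5, 1.5),
                        origin = c(0, 0, 0), surfaceZ = 0,
                        provenance = list()) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  methods::new("ImageVolume", voxels = voxels,
               voxelSize = as.numeric(voxelSize),
               origin = as.numeric(origin), surfaceZ = as.numeric(surfaceZ),
               provenance = provenance)
}

#' @describeIn ImageVolume Voxel intensity array.
#' @param x,object An `ImageVolume`.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname ImageVolume
#' @export
setMethod("voxels", "ImageVolume", function(x) x@voxels)

#' @rdname ImageVolume
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname ImageVolume
#' @export
setMethod("voxelSize", "ImageVolume", function(x) x@voxelSize)

#' @rdname ImageVolume
#' @export
setGeneric("volumeOrigin", function(x) standardGeneric("volumeOrigin"))
#' @rdname ImageVolume
#' @export
setMethod("volumeOrigin", "ImageVolume", function(x) x@origin)

#' @rdname ImageVolume
#' @export
setGeneric("surfaceZ", function(x) standardGeneric("surfaceZ"))
#' @rdname ImageVolume
#' @export
setMethod("surfaceZ", "ImageVolume", function(x) x@surfaceZ)

#' @rdname ImageVolume
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname ImageVolume
#' @export
setMethod("provenance", "ImageVolume", function(x) x@provenance)

#' Depth below the cortical surface of each z plane
#'
#' @param x An `ImageVolume`.
#' @return Numeric vector, one depth (um) per z plane.
#' @export
setGeneric("planeDepths", function(x) standardGeneric("planeDepths"))
#' @rdname planeDepths
#' @export
setMethod("planeDepths", "ImageVolume", function(x) {
  nz <- dim(x@voxels)[3]
  x@origin[3] + (seq_len(nz) - 1) * x@voxelSize[3] - x@surfaceZ
})

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@voxels)
  cat("ImageVolume ", paste(d, collapse = " x "),
      " voxels @ ", paste(signif(object@voxelSize, 4), collapse = " x "),
      " um\n", sep = "")
  cat("  origin (um):", paste(signif(object@origin, 5), collapse = ", "),
      " surfaceZ:", object@surfaceZ, "\n")
  cat("  intensity range:", paste(signif(range(object@voxels), 5),
                                  collapse = " .. "), "\n")
  if (length(object@provenance))
    cat("  provenance:", paste(vapply(object@provenance, `[[`, "", "step"),
                               collapse = " -> "), "\n")
})

## Convert world coordinates (n x 3, um) to continuous 1-based voxel coords.
worldToVoxel <- function(volume, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  sweep(sweep(pts, 2, volume@origin), 2, volume@voxelSize, "/") + 1
}

## Sample intensities at world coordinates by trilinear interpolation.
sampleIntensity <- function(volume, pts) {
  interpTrilinear(volume@voxels, worldToVoxel(volume, pts))
}

#' PSFModel: anisotropic, depth-varying Gaussian point spread function
#'
#' The PSF is an axis-aligned 3D Gaussian with a constant lateral FWHM and
#' an axial FWHM that grows linearly with depth below the cortical surface
#' (spherical aberration in cleared tissue imaged through a
#' water-immersion objective). A slope of 0 gives the depth-constant
#' in vivo case.
#'
#' @slot lateralFwhm Lateral (x/y) FWHM, um.
#' @slot axialFwhm0 Axial FWHM at depth 0, um.
#' @slot axialSlope Axial FWHM increase per um depth (um/um).
#' @export
setClass("PSFModel",
         representation(lateralFwhm = "numeric", axialFwhm0 = "numeric",
                        axialSlope = "numeric"))

setValidity("PSFModel", function(object) {
  if (object@lateralFwhm <= 0) return("lateralFwhm must be > 0")
  if (object@axialFwhm0 <= 0) return("axialFwhm0 must be > 0")
  TRUE
})

#' Construct a PSFModel
#'
#' Defaults follow the ex vivo calibration of a fructose-cleared
#' preparation: axial FWHM 3.4 um at the surface rising to 7.5 um at
#' 1 mm depth, i.e. slope (7.5 - 3.4)/1000 um/um.
#'
#' @param lateralFwhm Lateral FWHM in um (constant with depth).
#' @param axialFwhm0 Axial FWHM at the tissue surface, um.
#' @param axialSlope Axial FWHM change per um of depth; 0 for in vivo.
#' @return A [PSFModel-class] object.
#' @export
PSFModel <- function(lateralFwhm = 1.0, axialFwhm0 = 3.4,
                     axialSlope = (7.5 - 3.4) / 1000) {
  methods::new("PSFModel", lateralFwhm = as.numeric(lateralFwhm),
               axialFwhm0 = as.numeric(axialFwhm0),
               axialSlope = as.numeric(axialSlope))
}

#' @rdname PSFModel
#' @param x A `PSFModel`.
#' @export
setGeneric("lateralFwhm", function(x) standardGeneric("lateralFwhm"))
#' @rdname PSFModel
#' @export
setMethod("lateralFwhm", "PSFModel", function(x) x@lateralFwhm)

#' @rdname PSFModel
#' @export
setGeneric("axialFwhm0", function(x) standardGeneric("axialFwhm0"))
#' @rdname PSFModel
#' @export
setMethod("axialFwhm0", "PSFModel", function(x) x@axialFwhm0)

#' @rdname PSFModel
#' @export
setGeneric("axialSlope", function(x) standardGeneric("axialSlope"))
#' @rdname PSFModel
#' @export
setMethod("axialSlope", "PSFModel", function(x) x@axialSlope)

setMethod("show", "PSFModel", function(object) {
  cat("PSFModel: lateral FWHM ", signif(object@lateralFwhm, 4),
      " um; axial FWHM ", signif(object@axialFwhm0, 4), " um + ",
      signif(object@axialSlope, 4), " um/um depth\n", sep = "")
})

#' RefractiveScaling: index pair governing apparent axial step size
#'
#' Imaging a medium of refractive index `nAgent` with optics calibrated
#' for `nWater` stretches the true axial sampling by `nAgent/nWater`.
#'
#' @slot nAgent Refractive index of the clearing agent.
#' @slot nWater Refractive index of the immersion medium.
#' @export
setClass("RefractiveScaling",
         representation(nAgent = "numeric", nWater = "numeric"))

setValidity("RefractiveScaling", function(object) {
  if (object@nAgent <= 1 || object@nWater <= 1)
    return("refractive indices must exceed 1")
  TRUE
})

#' Construct a RefractiveScaling
#'
#' Defaults are the fructose clearing agent (1.49) against water (1.33).
#'
#' @param nAgent Refractive index of the clearing agent.
#' @param nWater Refractive index of the objective's immersion medium.
#' @return A [RefractiveScaling-class] object.
#' @export
RefractiveScaling <- function(nAgent = 1.49, nWater = 1.33) {
  methods::new("RefractiveScaling", nAgent = as.numeric(nAgent),
               nWater = as.numeric(nWater))
}

setMethod("show", "RefractiveScaling", function(object) {
  cat("RefractiveScaling: n_agent ", object@nAgent, " / n_water ",
      object@nWater, " = ", signif(object@nAgent / object@nWater, 4),
      "\n", sep = "")
})

#' VesselNetwork: a traced vascular graph
#'
#' Vertices are medial-atom samples of vessel centerlines (world position,
#' radius, tangent, local image signal, depth); edges connect consecutive
#' or branching vertices. After [buildSegments()] the edge set is
#' partitioned into segments: maximal paths whose interior vertices have
#' degree 2, i.e. the pieces of network between bifurcations and/or free
#' ends.
#'
#' @slot vertices data.frame with columns id, x, y, z, radius, tx, ty, tz,
#'   signal, depth, segment_id, cnr, label.
#' @slot edges Two-column integer matrix of vertex ids.
#' @slot segments data.frame of per-segment statistics (segment_id,
#'   n_vertices, arc_length, mean_radius, mean_signal, diameter,
#'   class_label, plus analysis columns).
#' @slot segmentPaths List of ordered vertex-id vectors, one per segment.
#' @export
setClass("VesselNetwork",
         representation(vertices = "data.frame", edges = "matrix",
                        segments = "data.frame", segmentPaths = "list"))

setValidity("VesselNetwork", function(object) {
  need <- c("id", "x", "y", "z", "radius")
  if (!all(need %in% names(object@vertices)))
    return(paste("vertices need columns:", paste(need, collapse = ", ")))
  e <- object@edges
  if (nrow(e) > 0) {
    if (ncol(e) != 2L) return("edges must have 2 columns")
    if (any(e[, 1] == e[, 2])) return("self-loop edges are not allowed")
    if (!all(e %in% object@vertices$id)) return("edge refers to unknown vertex")
  }
  TRUE
})

emptyVertexTable <- function() {
  data.frame(id = integer(), x = numeric(), y = numeric(), z = numeric(),
             radius = numeric(), tx = numeric(), ty = numeric(),
             tz = numeric(), signal = numeric(), depth = numeric(),
             segment_id = integer(), cnr = numeric(),
             label = character(), stringsAsFactors = FALSE)
}

#' Construct a VesselNetwork
#'
#' @param vertices data.frame with at least id, x, y, z, radius; missing
#'   optional columns (tangent, signal, depth, cnr, label) are added.
#' @param edges Two-column matrix/data.frame of vertex id pairs.
#' @return A [VesselNetwork-class] object (segments not yet built).
#' @seealso [buildSegments()]
#' @export
VesselNetwork <- function(vertices = emptyVertexTable(),
                          edges = matrix(integer(), ncol = 2)) {
  vertices <- as.data.frame(vertices)
  tmpl <- emptyVertexTable()
  for (cn in names(tmpl))
    if (!cn %in% names(vertices))
      vertices[[cn]] <- rep(tmpl[[cn]][NA_integer_][1] %||%
                              NA, nrow(vertices))
  vertices$label[is.na(vertices$label)] <- "unset"
  vertices <- vertices[, union(names(tmpl), names(vertices))]
  edges <- as.matrix(edges)
  if (nrow(edges)) storage.mode(edges) <- "integer"
  colnames(edges) <- c("id_a", "id_b")[seq_len(ncol(edges))]
  methods::new("VesselNetwork", vertices = vertices, edges = edges,
               segments = data.frame(), segmentPaths = list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn VesselNetwork Vertex table.
#' @param x,object A `VesselNetwork`.
#' @export
setGeneric("vertexTable", function(x) standardGeneric("vertexTable"))
#' @rdname VesselNetwork
#' @export
setMethod("vertexTable", "VesselNetwork", function(x) x@vertices)

#' @rdname VesselNetwork
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @rdname VesselNetwork
#' @export
setMethod("edgeTable", "VesselNetwork", function(x) x@edges)

#' @rdname VesselNetwork
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))
#' @rdname VesselNetwork
#' @export
setMethod("segmentTable", "VesselNetwork", function(x) x@segments)

#' @rdname VesselNetwork
#' @export
setGeneric("segmentPaths", function(x) standardGeneric("segmentPaths"))
#' @rdname VesselNetwork
#' @export
setMethod("segmentPaths", "VesselNetwork", function(x) x@segmentPaths)

setMethod("show", "VesselNetwork", function(object) {
  cat("VesselNetwork:", nrow(object@vertices), "vertices,",
      nrow(object@edges), "edges")
  if (nrow(object@segments)) cat(",", nrow(object@segments), "segments")
  cat("\n")
  if (nrow(object@segments) && "class_label" %in% names(object@segments)) {
    tb <- table(object@segments$class_label)
    cat("  segment classes:",
        paste(names(tb), tb, sep = ":", collapse = " "), "\n")
  }
})

#' TPSTransform: 3D thin-plate-spline mapping
#'
#' Interpolating thin-plate spline in three dimensions with the biharmonic
#' kernel U(r) = r, fitted to landmark pairs; maps each source landmark
#' exactly onto its target.
#'
#' @slot source n x 3 matrix of source landmarks (um).
#' @slot target n x 3 matrix of target landmarks (um).
#' @slot affine 4 x 3 affine coefficients (intercept row first).
#' @slot weights n x 3 kernel weights.
#' @export
setClass("TPSTransform",
         representation(source = "matrix", target = "matrix",
                        affine = "matrix", weights = "matrix"))

setMethod("show", "TPSTransform", function(object) {
  cat("TPSTransform:", nrow(object@source), "landmarks; bending energy",
      signif(tpsBendingEnergy(object), 4), "\n")
})
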
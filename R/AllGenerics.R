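#' Voxel spacing accessor
#' @param x an \linkS4class{ImageVolume} or \linkS4class{RoiMask}.
#' @return numeric(3) spacing in mm per (slice, row, column) axis.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Raw array accessor
#' @param x an \linkS4class{ImageVolume} or \linkS4class{RoiMask}.
#' @return the underlying 3D array.
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' Number of foreground voxels
#' @param x a \linkS4class{RoiMask}.
#' @return integer voxel count.
#' @export
setGeneric("voxelCount", function(x) standardGeneric("voxelCount"))

#' Bounding box of a mask
#' @param x a \linkS4class{RoiMask}.
#' @return 2x3 integer matrix: first row the minimum index per axis, second
#'   row the maximum.
#' @export
setGeneric("boundingBox", function(x) standardGeneric("boundingBox"))

#' @describeIn voxelSpacing spacing of a volume
#' @export
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacing)

#' @describeIn voxelSpacing spacing of a mask
#' @export
setMethod("voxelSpacing", "RoiMask", function(x) x@spacing)

#' @describeIn imgData HU array of a volume
#' @export
setMethod("imgData", "ImageVolume", function(x) x@data)

#' @describeIn imgData logical array of a mask
#' @export
setMethod("imgData", "RoiMask", function(x) x@data)

#' @describeIn voxelCount foreground voxel count
#' @export
setMethod("voxelCount", "RoiMask", function(x) sum(x@data))

#' @describeIn boundingBox inclusive index range of the foreground
#' @export
setMethod("boundingBox", "RoiMask", function(x) {
  idx <- which(x@data, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask has no bounding box")
  rbind(min = apply(idx, 2, min), max = apply(idx, 2, max))
})

#' @export
setMethod("dim", "ImageVolume", function(x) dim(x@data))

#' @export
setMethod("dim", "RoiMask", function(x) dim(x@data))

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume %d x %d x %d (slice x row x col), spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x ")))
  cat(sprintf("  HU range [%.1f, %.1f]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "RoiMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("RoiMask %d x %d x %d, %d foreground voxels\n",
              d[1], d[2], d[3], sum(object@data)))
})

setMethod("show", "Placement", function(object) {
  cat(sprintf("Placement in '%s': offset (%s), %d voxels%s\n",
              object@tissue, paste(object@offset, collapse = ", "),
              voxelCount(object@mask),
              if (object@usedZFallback) " [z-fallback]" else ""))
})

setMethod("show", "DecisionConfig", function(object) {
  cat(sprintf(
    "DecisionConfig: CV < %g%%, CCC > %g, fraction %g (%s), >= %d pairs, rule '%s'\n",
    object@cvThreshold, object@cccThreshold, object@patientFraction,
    if (object@inclusiveFraction) "inclusive" else "strict",
    object@minFailingPairs, object@combineRule))
})

setMethod("show", "UniquenessReport", function(object) {
  cat("UniquenessReport\n")
  cat(sprintf("  cohorts: %s\n", paste(object@cohorts, collapse = ", ")))
  for (nm in names(object@sets))
    cat(sprintf("  %-24s %d features\n", nm, length(object@sets[[nm]])))
})
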
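#' QuantizedRoi: gray-level quantized ROI
#'
#' Cropped to the mask bounding box; voxels outside the mask are NA.
#'
#' @slot levels 3D integer array of gray levels in 1..nLevels (NA outside the
#'   mask).
#' @slot nLevels number of gray levels.
#' @slot bounds numeric(2), the HU min and max of the ROI that map onto
#'   levels 1 and nLevels.
#' @slot nVoxels in-mask voxel count.
#' @export
setClass("QuantizedRoi",
  representation(levels = "array", nLevels = "integer", bounds = "numeric",
                 nVoxels = "integer"))

#' Equal-width gray-level quantization of an ROI
#'
#' Bins the ROI's own [min, max] HU range into \code{nLevels} equal-width
#' levels (half-open bins, maximum in the top bin). A constant ROI maps
#' entirely to level 1.
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param mask a non-empty \linkS4class{RoiMask} congruent with the volume.
#' @param nLevels number of gray levels (>= 2).
#' @return a \linkS4class{QuantizedRoi}.
#' @export
quantizeRoi <- function(volume, mask, nLevels = 64L) {
  if (!identical(dim(volume@data), dim(mask@data)))
    stop("mask must be congruent with the volume")
  if (!any(mask@data)) stop("mask is empty")
  if (nLevels < 2L) stop("nLevels must be >= 2")
  bb <- boundingBox(mask)
  sl <- lapply(1:3, function(k) bb["min", k]:bb["max", k])
  v <- volume@data[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
  m <- mask@data[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
  dim(v) <- dim(m) <- lengths(sl)
  lo <- min(v[m]); hi <- max(v[m])
  lev <- array(NA_integer_, dim = dim(v))
  if (hi > lo) {
    g <- floor((v[m] - lo) / (hi - lo) * nLevels) + 1L
    g[g > nLevels] <- as.integer(nLevels)
    lev[m] <- as.integer(g)
  } else {
    lev[m] <- 1L
  }
  new("QuantizedRoi", levels = lev, nLevels = as.integer(nLevels),
      bounds = c(lo, hi), nVoxels = as.integer(sum(m)))
}
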
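#' Gradient Orient Histogram features (9)
#'
#' Computes the in-plane intensity gradient per slice by central differences
#' (using volume values adjacent to the ROI, so border voxels of the mask
#' have well-defined gradients), bins the gradient orientation angles (in
#' degrees) into a magnitude-weighted histogram, and evaluates the
#' descriptive family on that weighted distribution. An all-zero gradient
#' field degenerates to a point mass at angle zero, for which every spread
#' statistic is 0.
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param mask a non-empty \linkS4class{RoiMask}.
#' @param params \code{extractionParams()}.
#' @return data.frame(feature, variant, value).
#' @export
gradientOrientFeatures <- function(volume, mask,
                                   params = extractionParams()) {
  cv <- cropVM(volume, mask, pad = 1L)
  v <- cv$v
  sp <- volume@spacing
  # central differences along rows (gy) and columns (gx), per slice
  gxp <- shiftArray(v, c(0L, 0L, -1L)); gxm <- shiftArray(v, c(0L, 0L, 1L))
  gyp <- shiftArray(v, c(0L, -1L, 0L)); gym <- shiftArray(v, c(0L, 1L, 0L))
  gx <- (gxp - gxm) / (2 * sp[3])
  gy <- (gyp - gym) / (2 * sp[2])
  use <- cv$m & !is.na(gx) & !is.na(gy)
  if (!any(use)) stop("no in-mask voxel has a computable in-plane gradient")
  ang <- atan2(gy[use], gx[use]) * 180 / pi      # [-180, 180)
  mag <- sqrt(gx[use]^2 + gy[use]^2)
  nb <- params$angleBins
  bw <- 360 / nb
  if (sum(mag) == 0) {
    centers <- 0
    wts <- 1
  } else {
    idx <- pmin(floor((ang + 180) / bw) + 1L, nb)
    wts <- vapply(seq_len(nb), function(k) sum(mag[idx == k]), numeric(1))
    centers <- -180 + (seq_len(nb) - 0.5) * bw
    keep <- wts > 0
    centers <- centers[keep]
    wts <- wts[keep]
  }
  histFamilyValues(centers, wts, bw, params$percentiles)
}
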
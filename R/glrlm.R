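# Extract the gray-level sequences of all lines of a slice matrix along an
# in-plane direction (dr, dc); out-of-mask voxels are NA and break runs.
sliceLines <- function(M, dr, dc) {
  if (dr == 0 && dc == 1) return(split(M, row(M)))
  if (dr == 1 && dc == 0) return(split(M, col(M)))
  if (dr == 1 && dc == 1) return(split(M, col(M) - row(M)))
  if (dr == 1 && dc == -1) return(split(M, col(M) + row(M)))
  stop("unsupported in-plane direction")
}

#' Gray-level run-length matrix of an ROI
#'
#' Builds the matrix of maximal constant-level runs along one in-plane
#' direction, pooled across all slices; out-of-mask voxels terminate runs.
#'
#' @param q a \linkS4class{QuantizedRoi}.
#' @param direction integer(3) with zero slice component, e.g. c(0, 0, 1).
#' @return integer matrix R[level, runLength].
#' @export
runLengthMatrix <- function(q, direction) {
  if (direction[1] != 0)
    stop("run-length directions are in-plane (zero slice component)")
  L <- q@levels
  d <- dim(L)
  maxLen <- max(d[2], d[3])
  R <- matrix(0L, q@nLevels, maxLen)
  for (s in seq_len(d[1])) {
    M <- matrix(L[s, , ], d[2], d[3])
    for (line in sliceLines(M, direction[2], direction[3])) {
      r <- rle(ifelse(is.na(line), -1L, line))
      keep <- r$values > 0
      if (!any(keep)) next
      for (k in which(keep))
        R[r$values[k], r$lengths[k]] <- R[r$values[k], r$lengths[k]] + 1L
    }
  }
  R
}

#' Run-length features along one direction
#'
#' The 11 standard gray-level run-length statistics computed from the pooled
#' run-length matrix: short/long run emphases, gray-level and run-length
#' nonuniformities, run percentage, low/high gray-level run emphases and the
#' four joint emphases.
#'
#' @param q a \linkS4class{QuantizedRoi}.
#' @param direction integer(3) in-plane direction.
#' @return named numeric of length 11.
#' @export
runLengthFeatures <- function(q, direction) {
  R <- runLengthMatrix(q, direction)
  nms <- glrlmFeatureNames()
  out <- stats::setNames(rep(NA_real_, length(nms)), nms)
  nr <- sum(R)
  if (nr == 0) return(out)
  np <- q@nVoxels
  i <- seq_len(nrow(R))              # gray level
  l <- seq_len(ncol(R))              # run length
  ri <- rowSums(R)                   # per-level totals
  rl <- colSums(R)                   # per-length totals
  I2 <- ri * i^2
  out["ShortRunEmphasis"] <- sum(rl / l^2) / nr
  out["LongRunEmphasis"] <- sum(rl * l^2) / nr
  out["GrayLevelNonuniformity"] <- sum(ri^2) / nr
  out["RunLengthNonuniformity"] <- sum(rl^2) / nr
  out["RunPercentage"] <- nr / np
  out["LowGrayLevelRunEmpha"] <- sum(ri / i^2) / nr
  out["HighGrayLevelRunEmpha"] <- sum(I2) / nr
  Li <- outer(1 / i^2, 1 / l^2)
  Hi <- outer(i^2, 1 / l^2)
  out["ShortRunLowGrayLevelEmpha"] <- sum(R * Li) / nr
  out["ShortRunHighGrayLevelEmpha"] <- sum(R * Hi) / nr
  out["LongRunLowGrayLevelEmpha"] <- sum(R * outer(1 / i^2, l^2)) / nr
  out["LongRunHighGrayLevelEmpha"] <- sum(R * outer(i^2, l^2)) / nr
  out
}
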
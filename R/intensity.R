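# Crop volume and mask to the mask bounding box expanded by `pad` voxels
# (clipped to the volume); returns HU array (values kept outside the mask)
# and the logical mask array.
cropVM <- function(volume, mask, pad = 0L) {
  if (!identical(dim(volume@data), dim(mask@data)))
    stop("mask must be congruent with the volume")
  if (!any(mask@data)) stop("mask is empty")
  bb <- boundingBox(mask)
  d <- dim(mask@data)
  sl <- lapply(1:3, function(k)
    max(1L, bb["min", k] - pad):min(d[k], bb["max", k] + pad))
  v <- volume@data[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
  m <- mask@data[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
  dim(v) <- dim(m) <- lengths(sl)
  list(v = v, m = m)
}

# The 9-member descriptive family evaluated on a discrete weighted
# distribution (support x, weights w, bin width for the area feature).
# Returns a data.frame(feature, variant, value).
histFamilyValues <- function(x, w, binwidth, percentiles) {
  st <- wStats(x, w)
  q <- wQuantile(st$x, st$w, c(0.25, 0.5, 0.75))
  med <- q[2]
  rows <- list(
    data.frame(feature = "InterQuartileRange", variant = "",
               value = q[3] - q[1]),
    data.frame(feature = "Kurtosis", variant = "", value = st$kurt),
    data.frame(feature = "MeanAbsoluteDeviation", variant = "",
               value = sum(st$w * abs(st$x - st$mean))),
    data.frame(feature = "MedianAbsoluteDeviation", variant = "",
               value = wQuantile(abs(st$x - med), st$w, 0.5)),
    data.frame(feature = "Range", variant = "",
               value = max(st$x) - min(st$x)),
    data.frame(feature = "Skewness", variant = "", value = st$skew)
  )
  pv <- wQuantile(st$x, st$w, percentiles / 100)
  rows <- c(rows, list(
    data.frame(feature = "Percentile", variant = sprintf("p%g", percentiles),
               value = pv),
    data.frame(feature = "Quantile", variant = sprintf("p%g", percentiles),
               value = wQuantileInterp(st$x, st$w, percentiles / 100)),
    data.frame(feature = "PercentileArea",
               variant = sprintf("p%g", percentiles),
               value = vapply(pv, function(q) binwidth * sum(w[x <= q]),
                              numeric(1)))
  ))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Linearly interpolated weighted quantile on the cumulative distribution.
wQuantileInterp <- function(x, w, p) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  if (length(x) == 1L) return(rep(x, length(p)))
  stats::approx(cw, x, xout = p, rule = 2, ties = "ordered")$y
}

#' Intensity Direct features (34)
#'
#' Global first-order statistics of the raw in-mask HU values plus local
#' sliding-window statistics. Entropy and uniformity use a 1-HU-wide bin
#' histogram. Local entropy, range and standard deviation are computed on a
#' 3x3 in-plane neighborhood restricted to in-mask voxels (entropy on the
#' 64-level quantized ROI), then summarized across voxels by max, mean,
#' median, min and std. Kurtosis is non-excess (normal = 3); mean/median
#' absolute deviations are unscaled.
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param mask a non-empty \linkS4class{RoiMask}.
#' @param params \code{extractionParams()}.
#' @return data.frame(feature, variant, value).
#' @export
intensityDirectFeatures <- function(volume, mask,
                                    params = extractionParams()) {
  cv <- cropVM(volume, mask, pad = 0L)
  v <- cv$v[cv$m]
  p <- histProbs(v)
  mu <- mean(v); med <- stats::median(v)
  scal <- c(
    Energy = sum(v^2),
    GlobalEntropy = entropyBits(p),
    GlobalMax = max(v), GlobalMean = mu, GlobalMedian = med,
    GlobalMin = min(v),
    GlobalStd = if (length(v) > 1) stats::sd(v) else 0,
    GlobalUniformity = sum(p^2),
    InterQuartileRange = unname(diff(stats::quantile(v, c(0.25, 0.75)))),
    Kurtosis = sampleKurtosis(v),
    MeanAbsoluteDeviation = mean(abs(v - mu)),
    MedianAbsoluteDeviation = stats::median(abs(v - med)),
    Range = max(v) - min(v),
    RootMeanSquare = sqrt(mean(v^2)),
    Skewness = sampleSkewness(v),
    Variance = if (length(v) > 1) stats::var(v) else 0
  )
  loc <- localStats(volume, mask, params)
  scal <- c(scal, loc)
  out <- data.frame(feature = names(scal), variant = "",
                    value = unname(scal))

  pct <- params$percentiles
  lv <- floor(v)
  centers <- seq(min(lv), max(lv))
  counts <- tabulate(lv - min(lv) + 1L, length(centers))
  pv <- unname(stats::quantile(v, pct / 100))
  out <- rbind(out,
    data.frame(feature = "Percentile", variant = sprintf("p%g", pct),
               value = pv),
    data.frame(feature = "Quantile", variant = sprintf("p%g", pct),
               value = wQuantileInterp(centers, counts, pct / 100)),
    data.frame(feature = "PercentileArea", variant = sprintf("p%g", pct),
               value = vapply(pv, function(q) sum(counts[centers <= q]),
                              numeric(1))))
  rownames(out) <- NULL
  out
}

# Local 3x3 in-plane neighborhood statistics, summarized across voxels.
localStats <- function(volume, mask, params) {
  cv <- cropVM(volume, mask, pad = 0L)
  vr <- cv$v; vr[!cv$m] <- NA_real_
  q <- quantizeRoi(volume, mask, params$nLevels)
  lq <- q@levels
  offs <- expand.grid(ds = 0L, dr = -1:1, dc = -1:1)
  n <- sum(cv$m)
  rawN <- matrix(NA_real_, n, nrow(offs))
  levN <- matrix(NA_integer_, n, nrow(offs))
  for (k in seq_len(nrow(offs))) {
    o <- as.integer(offs[k, ])
    rawN[, k] <- shiftArray(vr, -o)[cv$m]
    levN[, k] <- shiftArray(lq, -o)[cv$m]
  }
  rng <- apply(rawN, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0) 0 else max(r) - min(r)
  })
  sdv <- apply(rawN, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) < 2) 0 else stats::sd(r)
  })
  ent <- apply(levN, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0) return(0)
    entropyBits(tabulate(r) / length(r))
  })
  summarize <- function(x, nm) {
    stats::setNames(
      c(max(x), mean(x), stats::median(x), min(x),
        if (length(x) > 1) stats::sd(x) else 0),
      paste0(nm, c("Max", "Mean", "Median", "Min", "Std")))
  }
  c(summarize(ent, "LocalEntropy")[c(1, 2, 3, 4, 5)],
    summarize(rng, "LocalRange"),
    summarize(sdv, "LocalStd"))
}

#' Intensity Histogram features (9)
#'
#' The descriptive family (interquartile range, kurtosis, mean/median
#' absolute deviation, percentiles, percentile areas, quantiles, range,
#' skewness) evaluated on the equal-width binned intensity histogram of the
#' ROI (bin centers weighted by counts).
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param mask a non-empty \linkS4class{RoiMask}.
#' @param params \code{extractionParams()}.
#' @return data.frame(feature, variant, value).
#' @export
intensityHistogramFeatures <- function(volume, mask,
                                       params = extractionParams()) {
  cv <- cropVM(volume, mask, pad = 0L)
  v <- cv$v[cv$m]
  lo <- min(v); hi <- max(v)
  nb <- params$histBins
  if (hi > lo) {
    bw <- (hi - lo) / nb
    idx <- pmin(floor((v - lo) / bw) + 1L, nb)
    counts <- tabulate(idx, nb)
    centers <- lo + (seq_len(nb) - 0.5) * bw
  } else {
    bw <- 1
    counts <- length(v)
    centers <- lo
  }
  histFamilyValues(centers, counts, bw, params$percentiles)
}
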
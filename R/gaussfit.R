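#' Intensity Histogram Gauss Fit features (6)
#'
#' Fits a univariate Gaussian mixture (1 to \code{maxGauss} components,
#' unequal variances, BIC model selection via \pkg{mclust}) to the in-mask HU
#' values and reports the dominant component's amplitude, area, mean and
#' standard deviation, the total histogram area, and the number of fitted
#' components. The histogram is on 1-HU-wide bins, so HistArea equals the
#' voxel count; component area is voxel count times mixing proportion and
#' amplitude is the component density peak scaled to histogram counts.
#' Initialization is deterministic (evenly spaced subset), so identical input
#' gives an identical fit. Non-convergence falls back to a single-Gaussian
#' moment fit.
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param mask a non-empty \linkS4class{RoiMask}.
#' @param params \code{extractionParams()}.
#' @return named numeric of length 6.
#' @importFrom mclust Mclust mclustBIC
#' @export
gaussFitFeatures <- function(volume, mask, params = extractionParams()) {
  cv <- cropVM(volume, mask, pad = 0L)
  v <- cv$v[cv$m]
  n <- length(v)
  histArea <- n                      # 1-HU bins: area = voxel count
  if (stats::sd(v) == 0 || n < 10L) {
    return(c(GaussAmplitude = histArea, GaussArea = histArea,
             GaussMean = mean(v), GaussStd = 0, HistArea = histArea,
             NumberOfGauss = 1))
  }
  sub <- unique(round(seq(1L, n, length.out = min(n, 2000L))))
  fit <- tryCatch(
    suppressWarnings(Mclust(v, G = seq_len(params$maxGauss),
                            modelNames = "V", verbose = FALSE,
                            initialization = list(subset = sub))),
    error = function(e) NULL)
  if (is.null(fit)) {
    mu <- mean(v); sg <- stats::sd(v)
    return(c(GaussAmplitude = histArea / (sg * sqrt(2 * pi)),
             GaussArea = histArea, GaussMean = mu, GaussStd = sg,
             HistArea = histArea, NumberOfGauss = 1))
  }
  pro <- fit$parameters$pro
  mus <- fit$parameters$mean
  sig <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sig) == 1L) sig <- rep(sig, length(pro))
  k <- which.max(pro)
  amp <- if (sig[k] > 0) histArea * pro[k] / (sig[k] * sqrt(2 * pi))
         else histArea * pro[k]
  c(GaussAmplitude = amp, GaussArea = histArea * pro[k],
    GaussMean = unname(mus[k]), GaussStd = unname(sig[k]),
    HistArea = histArea, NumberOfGauss = fit$G)
}
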
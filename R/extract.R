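#' Extract all registry features from one ROI placement
#'
#' Runs the seven feature families on the raw (unpreprocessed) volume and
#' mask and returns one value per (category, feature, variant) key of the
#' registry expansion. 2D categories are computed slice-wise with pair/run
#' counts pooled across slices; 3D categories use the full ROI. Undefined
#' values (e.g. texture features of a single-level ROI) are carried as NA,
#' never silently zero, and do not abort the remaining features.
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param mask a non-empty congruent \linkS4class{RoiMask}.
#' @param registry \code{featureRegistry()}.
#' @param params \code{extractionParams()}.
#' @return data.frame(category, feature, variant, value) in registry order.
#' @export
extractFeatures <- function(volume, mask, registry = featureRegistry(),
                            params = extractionParams()) {
  if (!any(mask@data)) stop("mask is empty")
  q <- quantizeRoi(volume, mask, params$nLevels)

  named2df <- function(category, x, variant = "") {
    data.frame(category = category, feature = names(x), variant = variant,
               value = unname(x), stringsAsFactors = FALSE)
  }
  safely <- function(expr, fallbackNames, category, variant = "") {
    val <- tryCatch(expr, error = function(e)
      stats::setNames(rep(NA_real_, length(fallbackNames)), fallbackNames))
    named2df(category, val, variant)
  }

  rows <- list()
  for (k in seq_len(nrow(directions2D()))) {
    d <- directions2D()[k, ]
    rows[[length(rows) + 1L]] <-
      safely(glcmFeatures(computeGlcm(q, d)), glcmFeatureNames(),
             "GLCM2D", directionLabel(d))
    rows[[length(rows) + 1L]] <-
      safely(runLengthFeatures(q, d), glrlmFeatureNames(),
             "GrayRunLength2D", directionLabel(d))
  }
  for (k in seq_len(nrow(directions3D()))) {
    d <- directions3D()[k, ]
    rows[[length(rows) + 1L]] <-
      safely(glcmFeatures(computeGlcm(q, d)), glcmFeatureNames(),
             "GLCM3D", directionLabel(d))
  }
  addDf <- function(category, expr, nFeat) {
    df <- tryCatch(expr, error = function(e) NULL)
    if (is.null(df)) return(NULL)
    df$category <- category
    df[, c("category", "feature", "variant", "value")]
  }
  rows[[length(rows) + 1L]] <-
    addDf("IntensityDirect", intensityDirectFeatures(volume, mask, params))
  rows[[length(rows) + 1L]] <-
    addDf("IntensityHistogram",
          intensityHistogramFeatures(volume, mask, params))
  rows[[length(rows) + 1L]] <-
    named2df("IntensityHistGaussFit", gaussFitFeatures(volume, mask, params))
  rows[[length(rows) + 1L]] <-
    safely(nidFeatures(q, "2D"), ngtdmFeatureNames(),
           "NeighborIntensityDiff2D")
  rows[[length(rows) + 1L]] <-
    safely(nidFeatures(q, "3D"), ngtdmFeatureNames(),
           "NeighborIntensityDiff3D")
  rows[[length(rows) + 1L]] <-
    addDf("GradientOrientHistogram",
          gradientOrientFeatures(volume, mask, params))

  got <- do.call(rbind, rows)
  exp <- registryExpansion(registry, params)
  out <- merge(exp, got, by = c("category", "feature", "variant"),
               all.x = TRUE, sort = FALSE)
  # restore registry order
  key <- function(df) paste(df$category, df$feature, df$variant, sep = "\r")
  out <- out[match(key(exp), key(out)), ]
  rownames(out) <- NULL
  out
}
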
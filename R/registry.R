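# Directional offsets are expressed as (slice, row, column) voxel steps.
directions2D <- function() {
  rbind(c(0, 0, 1), c(0, 1, 0), c(0, 1, 1), c(0, 1, -1))
}

directions3D <- function() {
  rbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0),
        c(0, 1, 1), c(0, 1, -1), c(1, 0, 1), c(1, 0, -1),
        c(1, 1, 0), c(1, -1, 0),
        c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

directionLabel <- function(d) sprintf("d(%d,%d,%d)", d[1], d[2], d[3])

#' Default extraction parameters
#'
#' @param nLevels gray levels for quantization (default 64).
#' @param percentiles percentile grid for percentile-based variants
#'   (default 10, 20, ..., 90).
#' @param histBins number of equal-width bins for the intensity histogram
#'   category (default 256).
#' @param angleBins number of orientation bins (10 degrees each) for the
#'   gradient orientation histogram (default 36).
#' @param maxGauss maximum number of mixture components for the Gaussian
#'   histogram fit (default 3).
#' @return named list of parameters.
#' @export
extractionParams <- function(nLevels = 64L, percentiles = seq(10, 90, by = 10),
                             histBins = 256L, angleBins = 36L,
                             maxGauss = 3L) {
  list(nLevels = as.integer(nLevels), percentiles = percentiles,
       histBins = as.integer(histBins), angleBins = as.integer(angleBins),
       maxGauss = as.integer(maxGauss))
}

# The 9-member descriptive-statistics family shared by the intensity
# histogram and gradient orientation histogram categories.
histFamilyNames <- function() {
  c("InterQuartileRange", "Kurtosis", "MeanAbsoluteDeviation",
    "MedianAbsoluteDeviation", "Percentile", "PercentileArea", "Quantile",
    "Range", "Skewness")
}

# The 22 gray-level co-occurrence features (computed per direction).
glcmFeatureNames <- function() {
  c("AutoCorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
    "Contrast", "Correlation", "DifferenceEntropy", "Dissimilarity", "Energy",
    "Entropy", "Homogeneity", "Homogeneity2", "InformationMeasureCorr1",
    "InformationMeasureCorr2", "InverseDiffMomentNorm", "InverseDiffNorm",
    "InverseVariance", "MaxProbability", "SumAverage", "SumEntropy",
    "SumVariance", "Variance")
}

glrlmFeatureNames <- function() {
  c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonuniformity",
    "RunLengthNonuniformity", "RunPercentage", "LowGrayLevelRunEmpha",
    "HighGrayLevelRunEmpha", "ShortRunLowGrayLevelEmpha",
    "ShortRunHighGrayLevelEmpha", "LongRunLowGrayLevelEmpha",
    "LongRunHighGrayLevelEmpha")
}

ngtdmFeatureNames <- function() {
  c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")
}

#' The 123-feature radiomic registry
#'
#' One row per feature with its category, variant axis (none, directions2d,
#' directions3d or percentiles) and a flag for names reconstructed from the
#' IBEX feature lineage rather than printed in the source tables. Category
#' cardinalities are fixed: IntensityDirect 34, IntensityHistogram 9,
#' IntensityHistGaussFit 6, GLCM2D 22, GLCM3D 22, GrayRunLength2D 11,
#' NeighborIntensityDiff2D 5, NeighborIntensityDiff3D 5,
#' GradientOrientHistogram 9 (total 123).
#'
#' @return data.frame with columns category, feature, variantAxis,
#'   reconstructed.
#' @export
featureRegistry <- function() {
  idTable <- c("GlobalEntropy", "GlobalMax", "GlobalStd", "GlobalUniformity",
               "Kurtosis", "LocalEntropyMax", "LocalEntropyMean",
               "LocalEntropyMedian", "LocalEntropyMin", "LocalEntropyStd",
               "LocalRangeMax", "LocalRangeMean", "LocalRangeMedian",
               "LocalRangeMin", "LocalRangeStd", "LocalStdMax",
               "LocalStdMean", "LocalStdMin", "LocalStdStd", "Range")
  idExtra <- c("Energy", "GlobalMean", "GlobalMedian", "GlobalMin",
               "InterQuartileRange", "LocalStdMedian",
               "MeanAbsoluteDeviation", "MedianAbsoluteDeviation",
               "Percentile", "PercentileArea", "Quantile", "RootMeanSquare",
               "Skewness", "Variance")
  pctFeats <- c("Percentile", "PercentileArea", "Quantile")
  rows <- list(
    data.frame(category = "IntensityDirect",
               feature = c(idTable, idExtra),
               reconstructed = rep(c(FALSE, TRUE),
                                   c(length(idTable), length(idExtra)))),
    data.frame(category = "IntensityHistogram", feature = histFamilyNames(),
               reconstructed = histFamilyNames() != "Range"),
    data.frame(category = "IntensityHistGaussFit",
               feature = c("GaussAmplitude", "GaussArea", "GaussMean",
                           "GaussStd", "HistArea", "NumberOfGauss"),
               reconstructed = FALSE),
    data.frame(category = "GLCM2D", feature = glcmFeatureNames(),
               reconstructed = FALSE),
    data.frame(category = "GLCM3D", feature = glcmFeatureNames(),
               reconstructed = FALSE),
    data.frame(category = "GrayRunLength2D", feature = glrlmFeatureNames(),
               reconstructed = FALSE),
    data.frame(category = "NeighborIntensityDiff2D",
               feature = ngtdmFeatureNames(), reconstructed = FALSE),
    data.frame(category = "NeighborIntensityDiff3D",
               feature = ngtdmFeatureNames(), reconstructed = FALSE),
    data.frame(category = "GradientOrientHistogram",
               feature = histFamilyNames(), reconstructed = FALSE)
  )
  reg <- do.call(rbind, rows)
  reg$variantAxis <- "none"
  reg$variantAxis[reg$category %in% c("GLCM2D", "GrayRunLength2D")] <-
    "directions2d"
  reg$variantAxis[reg$category == "GLCM3D"] <- "directions3d"
  pctCats <- c("IntensityDirect", "IntensityHistogram",
               "GradientOrientHistogram")
  reg$variantAxis[reg$category %in% pctCats & reg$feature %in% pctFeats] <-
    "percentiles"
  rownames(reg) <- NULL
  reg[, c("category", "feature", "variantAxis", "reconstructed")]
}

#' Expand the registry into (category, feature, variant) keys
#'
#' Scalar features get a single empty variant; directional features one
#' variant per offset direction; percentile features one per percentile on
#' the configured grid.
#'
#' @param registry output of \code{featureRegistry()}.
#' @param params output of \code{extractionParams()}.
#' @return data.frame with columns category, feature, variant.
#' @export
registryExpansion <- function(registry = featureRegistry(),
                              params = extractionParams()) {
  d2 <- apply(directions2D(), 1, directionLabel)
  d3 <- apply(directions3D(), 1, directionLabel)
  pct <- sprintf("p%g", params$percentiles)
  variants <- function(axis) switch(axis, none = "", directions2d = d2,
                                    directions3d = d3, percentiles = pct)
  out <- do.call(rbind, lapply(seq_len(nrow(registry)), function(i) {
    v <- variants(registry$variantAxis[i])
    data.frame(category = registry$category[i], feature = registry$feature[i],
               variant = v, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
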
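featVal <- function(df, feature, variant = "") {
  df$value[df$feature == feature & df$variant == variant]
}

test_that("a constant ROI zeroes all spread statistics", {
  vol <- ImageVolume(array(50, c(2, 4, 4)))
  mask <- RoiMask(array(TRUE, c(2, 4, 4)))
  f <- intensityDirectFeatures(vol, mask)
  expect_equal(featVal(f, "GlobalStd"), 0)
  expect_equal(featVal(f, "Range"), 0)
  expect_equal(featVal(f, "GlobalUniformity"), 1)
  for (nm in c("LocalEntropyMax", "LocalEntropyMean", "LocalEntropyMedian",
               "LocalEntropyMin", "LocalEntropyStd"))
    expect_equal(featVal(f, nm), 0, label = nm)
  h <- intensityHistogramFeatures(vol, mask)
  expect_equal(featVal(h, "Range"), 0)
  expect_equal(featVal(h, "InterQuartileRange"), 0)
})

test_that("order statistics of 1..100 are exact", {
  vol <- ImageVolume(array(as.numeric(1:100), c(1, 10, 10)))
  mask <- RoiMask(array(TRUE, c(1, 10, 10)))
  f <- intensityDirectFeatures(vol, mask)
  expect_equal(featVal(f, "GlobalMax"), 100)
  expect_equal(featVal(f, "GlobalMin"), 1)
  expect_equal(featVal(f, "Range"), 99)
  expect_equal(featVal(f, "GlobalMedian"), 50.5)
  expect_equal(featVal(f, "GlobalMean"), 50.5)
})

test_that("kurtosis matches a direct moment-ratio evaluation", {
  v <- c(0, 0, 0, 100)
  vol <- ImageVolume(array(v, c(1, 1, 4)))
  mask <- RoiMask(array(TRUE, c(1, 1, 4)))
  f <- intensityDirectFeatures(vol, mask)
  m <- mean(v)
  direct <- mean((v - m)^4) / mean((v - m)^2)^2   # brute-force moments
  expect_equal(featVal(f, "Kurtosis"), direct)
  expect_equal(direct, 7 / 3)
})

test_that("histogram entropy follows the closed forms", {
  # uniform over k bins: log2 k bits
  expect_equal(radUnique:::entropyBits(rep(1 / 8, 8)), 3)
  # two-bin (0.25, 0.75): 0.8113 bits
  expect_equal(radUnique:::entropyBits(c(0.25, 0.75)), 0.8112781,
               tolerance = 1e-6)
  # GlobalEntropy of a two-value ROI at 1:3 odds reproduces the same number
  vol <- ImageVolume(array(c(0, 10, 10, 10), c(1, 1, 4)))
  mask <- RoiMask(array(TRUE, c(1, 1, 4)))
  f <- intensityDirectFeatures(vol, mask)
  expect_equal(featVal(f, "GlobalEntropy"), 0.8112781, tolerance = 1e-6)
})

test_that("percentile variants follow the configured grid", {
  vol <- ImageVolume(array(as.numeric(1:100), c(1, 10, 10)))
  mask <- RoiMask(array(TRUE, c(1, 10, 10)))
  f <- intensityDirectFeatures(vol, mask)
  expect_equal(featVal(f, "Percentile", "p50"),
               unname(quantile(1:100, 0.5)))
  expect_equal(length(f$value[f$feature == "Percentile"]), 9L)
  h <- intensityHistogramFeatures(vol, mask)
  expect_equal(length(h$value[h$feature == "Quantile"]), 9L)
})

test_that("local statistics honor the in-mask 3x3 in-plane window", {
  # two-voxel mask: each neighborhood is the pair, range = 10, sd = sqrt(50)
  vol <- ImageVolume(array(c(0, 10), c(1, 1, 2)))
  mask <- RoiMask(array(TRUE, c(1, 1, 2)))
  f <- intensityDirectFeatures(vol, mask)
  expect_equal(featVal(f, "LocalRangeMax"), 10)
  expect_equal(featVal(f, "LocalRangeMin"), 10)
  expect_equal(featVal(f, "LocalStdMax"), sd(c(0, 10)))
  expect_equal(featVal(f, "LocalEntropyMax"), 1)  # two levels, equal mass
})
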
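test_that("the registry has 123 features with the published cardinalities", {
  reg <- featureRegistry()
  expect_equal(nrow(reg), 123L)
  counts <- table(reg$category)
  expect_equal(unname(counts[["IntensityDirect"]]), 34L)
  expect_equal(unname(counts[["IntensityHistogram"]]), 9L)
  expect_equal(unname(counts[["IntensityHistGaussFit"]]), 6L)
  expect_equal(unname(counts[["GLCM2D"]] + counts[["GLCM3D"]]), 44L)
  expect_equal(unname(counts[["GrayRunLength2D"]]), 11L)
  expect_equal(unname(counts[["NeighborIntensityDiff2D"]] +
                        counts[["NeighborIntensityDiff3D"]]), 10L)
  expect_equal(unname(counts[["GradientOrientHistogram"]]), 9L)
  expect_false(any(duplicated(paste(reg$category, reg$feature))))
})

test_that("every feature printed in the source tables is registered", {
  reg <- featureRegistry()
  counts <- loadReplayCounts()
  key <- paste(reg$category, reg$feature)
  for (df in c(counts$cv, counts$ccc))
    expect_true(all(paste(df$category, df$feature) %in% key))
})

test_that("extraction yields one value per registry expansion key", {
  ph <- generatePhantom(PhantomSpec(dims = c(16, 40, 40), noduleDiameter = 8,
                                    seed = 21L))
  fv <- extractFeatures(phantomVolume(ph), noduleMask(ph))
  exp <- registryExpansion()
  expect_identical(fv[, c("category", "feature", "variant")], exp)
  expect_false(any(is.na(fv$value)))
  # per-feature coverage of all 123 names
  expect_equal(length(unique(paste(fv$category, fv$feature))), 123L)
})

test_that("extraction is deterministic", {
  ph <- generatePhantom(PhantomSpec(dims = c(16, 32, 32), noduleDiameter = 6,
                                    seed = 8L))
  a <- extractFeatures(phantomVolume(ph), noduleMask(ph))
  b <- extractFeatures(phantomVolume(ph), noduleMask(ph))
  expect_identical(a, b)
})

test_that("features are invariant under joint rigid translation", {
  set.seed(77)
  d <- c(8, 14, 14)
  content <- array(rnorm(4 * 5 * 5, sd = 50), c(4, 5, 5))
  embed <- function(at) {
    v <- array(-1000, d)
    v[at[1]:(at[1] + 3), at[2]:(at[2] + 4), at[3]:(at[3] + 4)] <- content
    m <- array(FALSE, d)
    m[(at[1] + 1):(at[1] + 2), (at[2] + 1):(at[2] + 3),
      (at[3] + 1):(at[3] + 3)] <- TRUE
    list(vol = ImageVolume(v), mask = RoiMask(m))
  }
  a <- embed(c(2, 3, 3))
  b <- embed(c(3, 6, 8))
  expect_equal(extractFeatures(a$vol, a$mask), extractFeatures(b$vol, b$mask))
})

test_that("a translated constant-field ROI extracts identically", {
  d <- c(6, 12, 12)
  vol <- ImageVolume(array(30, d))
  m1 <- array(FALSE, d); m1[2:4, 2:5, 2:5] <- TRUE
  m2 <- array(FALSE, d); m2[3:5, 6:9, 7:10] <- TRUE
  expect_equal(extractFeatures(vol, RoiMask(m1)),
               extractFeatures(vol, RoiMask(m2)))
})

test_that("undefined values propagate without aborting other features", {
  # single-voxel ROI: texture matrices have no pairs, first-order still works
  d <- c(3, 5, 5)
  vol <- ImageVolume(array(rnorm(prod(d)), d))
  m <- array(FALSE, d); m[2, 3, 3] <- TRUE
  fv <- extractFeatures(vol, RoiMask(m))
  expect_true(all(is.na(fv$value[fv$category == "NeighborIntensityDiff3D"])))
  expect_false(any(is.na(fv$value[fv$feature == "GlobalMean"])))
})
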
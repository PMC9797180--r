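test_that("equal-width quantization matches hand-binned examples", {
  vol <- ImageVolume(array(c(0, 10, 20, 30), c(1, 1, 4)))
  mask <- RoiMask(array(TRUE, c(1, 1, 4)))
  q <- quantizeRoi(vol, mask, 2)
  expect_identical(as.integer(q@levels), c(1L, 1L, 2L, 2L))
  # constant ROI: everything level 1
  qc <- quantizeRoi(ImageVolume(array(7, c(1, 2, 2))),
                    RoiMask(array(TRUE, c(1, 2, 2))), 8)
  expect_true(all(qc@levels == 1L))
  # equally spaced values with nLevels = #distinct: bijective assignment
  vb <- ImageVolume(array(c(0, 5, 10, 15), c(1, 1, 4)))
  qb <- quantizeRoi(vb, RoiMask(array(TRUE, c(1, 1, 4))), 4)
  expect_identical(as.integer(qb@levels), 1:4)
  expect_error(quantizeRoi(vb, RoiMask(array(TRUE, c(1, 1, 4))), 1), ">= 2")
})

# the 2x2 single-slice worked example: levels [[1,1],[1,2]]
example2x2 <- function() {
  vol <- ImageVolume(array(c(0, 0, 0, 10), c(1, 2, 2)))
  mask <- RoiMask(array(TRUE, c(1, 2, 2)))
  quantizeRoi(vol, mask, 2)
}

test_that("co-occurrence probabilities match hand enumeration", {
  q <- example2x2()
  g <- computeGlcm(q, c(0, 0, 1), 1, symmetric = TRUE)
  expect_equal(g@p, matrix(c(0.5, 0.25, 0.25, 0), 2, 2, byrow = TRUE))
  ga <- computeGlcm(q, c(0, 0, 1), 1, symmetric = FALSE)
  expect_equal(ga@p, matrix(c(0.5, 0.5, 0, 0), 2, 2, byrow = TRUE))
  # constant ROI: all mass at p(1,1)
  qc <- quantizeRoi(ImageVolume(array(5, c(1, 2, 2))),
                    RoiMask(array(TRUE, c(1, 2, 2))), 2)
  gc <- computeGlcm(qc, c(0, 0, 1))
  expect_equal(gc@p[1, 1], 1)
  # zero pairs: explicitly empty matrix, features undefined
  g0 <- computeGlcm(q, c(1, 0, 0))       # single-slice ROI, slice offset
  expect_identical(g0@nPairs, 0L)
  expect_true(all(is.na(glcmFeatures(g0))))
})

test_that("Haralick features match the hand-summed 2x2 example", {
  f <- glcmFeatures(computeGlcm(example2x2(), c(0, 0, 1)))
  expect_equal(unname(f["Energy"]), 0.375)
  expect_equal(unname(f["Entropy"]), 1.5)
  expect_equal(unname(f["InverseDiffNorm"]), 0.5 + 0.5 / 1.5)
  expect_equal(unname(f["InverseDiffMomentNorm"]), 0.9)
  expect_equal(unname(f["MaxProbability"]), 0.5)
})

test_that("a constant ROI is a delta distribution", {
  qc <- quantizeRoi(ImageVolume(array(5, c(1, 3, 3))),
                    RoiMask(array(TRUE, c(1, 3, 3))), 4)
  f <- glcmFeatures(computeGlcm(qc, c(0, 0, 1)))
  expect_equal(unname(f["Energy"]), 1)
  expect_equal(unname(f["Entropy"]), 0)
  expect_equal(unname(f["InverseDiffNorm"]), 1)
  expect_equal(unname(f["InverseDiffMomentNorm"]), 1)
  expect_equal(unname(f["MaxProbability"]), 1)
})

test_that("matrices conserve mass and respect the symmetry flag", {
  for (seed in 1:5) {
    roi <- makeSmallRoi(seed)
    g <- computeGlcm(roi$q, c(0, 1, 1))
    if (g@nPairs > 0) {
      expect_lt(abs(sum(g@p) - 1), 1e-12)
      expect_equal(g@p, t(g@p))
    }
  }
})

test_that("normalized homogeneities dominate their unnormalized forms", {
  for (seed in 1:5) {
    roi <- makeSmallRoi(seed, nLevels = 6)
    for (dir in list(c(0, 0, 1), c(1, 0, 0), c(0, 1, -1))) {
      g <- computeGlcm(roi$q, dir)
      if (g@nPairs == 0) next
      f <- glcmFeatures(g)
      expect_gte(f[["InverseDiffNorm"]], f[["Homogeneity"]])
      expect_gte(f[["InverseDiffMomentNorm"]], f[["Homogeneity2"]])
    }
  }
})

test_that("all GLCM features match brute-force enumeration on small ROIs", {
  dirs <- list(c(0, 0, 1), c(0, 1, 0), c(0, 1, -1), c(1, 0, 0), c(1, 1, 1))
  for (seed in 1:4) {
    roi <- makeSmallRoi(seed, dims = c(3, 5, 5), nLevels = 4)
    for (dir in dirs) for (sym in c(TRUE, FALSE)) {
      g <- computeGlcm(roi$q, dir, symmetric = sym)
      pb <- bruteGlcm(roi$q@levels, 4, dir, symmetric = sym)
      expect_equal(g@p, pb, tolerance = 1e-12)
      if (g@nPairs > 0) {
        got <- glcmFeatures(g)
        want <- oracleGlcmFeatures(pb)
        expect_equal(got[names(want)], want, tolerance = 1e-10)
      }
    }
  }
})
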
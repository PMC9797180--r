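# A tiny labeled grid: label value 1 everywhere except where overridden.
gridLabels <- function(d) array(1L, dim = d)

test_that("a target region equal to the ROI itself yields the identity", {
  d <- c(3, 6, 6)
  m <- array(FALSE, d)
  m[2, 2:4, 3] <- TRUE
  lab <- gridLabels(d)
  lab[m] <- 5L
  pl <- findPlacements(RoiMask(m), lab, targets = "nodule",
                       tissueLevels = c(nodule = 5L), seed = 1)$nodule
  expect_identical(pl@offset, c(0L, 0L, 0L))
  expect_identical(imgData(pl@mask), m)
  expect_false(pl@usedZFallback)
})

test_that("a single-voxel ROI places in-plane whenever the slice has room", {
  d <- c(3, 5, 5)
  m <- array(FALSE, d)
  m[2, 3, 3] <- TRUE
  lab <- gridLabels(d)
  lab[2, 1, 1] <- 2L
  pl <- findPlacements(RoiMask(m), lab, targets = "adipose",
                       tissueLevels = c(adipose = 2L), seed = 1)$adipose
  expect_false(pl@usedZFallback)
  expect_identical(voxelCount(pl@mask), 1L)
  expect_identical(unname(which(imgData(pl@mask), arr.ind = TRUE)[1, ]),
                   c(2L, 1L, 1L))
})

test_that("z-fallback triggers only when no in-plane offset fits", {
  d <- c(6, 12, 12)
  m <- array(FALSE, d)
  m[2, 5, 6] <- m[2, 6, 5] <- m[2, 6, 6] <- m[2, 6, 7] <- m[2, 7, 6] <- TRUE
  lab <- array(9L, d)
  lab[2, 3, 3:4] <- 2L                 # 2-voxel strip in the ROI's slice
  lab[5, 2:11, 2:11] <- 2L             # roomy patch 3 slices away
  tumor <- RoiMask(m)
  pl <- findPlacements(tumor, lab, targets = "adipose",
                       tissueLevels = c(adipose = 2L), seed = 4)$adipose
  expect_true(pl@usedZFallback)
  expect_identical(pl@offset[1], 3L)
  # brute-force enumeration: no valid in-plane offset exists
  valid <- bruteValidOffsets(m, lab == 2L)
  expect_true(all(valid[, 1] != 0))
  # and the FFT search agrees with brute force on the chosen plane
  expect_true(any(valid[, 1] == 3))
})

test_that("FFT placement search agrees with brute-force enumeration", {
  for (seed in 1:3) {
    set.seed(seed)
    d <- c(4, 9, 9)
    m <- array(FALSE, d)
    m[2:3, 4:6, 4:6] <- array(runif(18) > 0.4, c(2, 3, 3))
    if (!any(m)) m[2, 4, 4] <- TRUE
    lab <- array(as.integer(runif(prod(d)) > 0.25), d)
    expected <- bruteValidOffsets(m, lab == 1L)
    pl <- suppressWarnings(
      findPlacements(RoiMask(m), lab, targets = "t",
                     tissueLevels = c(t = 1L), seed = seed)$t)
    if (is.null(expected)) {
      expect_null(pl)
    } else {
      expect_true(any(apply(expected, 1, function(r) all(r == pl@offset))))
      # preferred group: the minimal |dz| present among valid offsets
      expect_identical(abs(pl@offset[1]), min(abs(expected[, 1])))
    }
  }
})

test_that("placements preserve voxel count and internal geometry", {
  ph <- generatePhantom(PhantomSpec(dims = c(16, 48, 48), noduleDiameter = 8,
                                    seed = 9L))
  tumor <- noduleMask(ph)
  pls <- findPlacements(tumor, tissueLabels(ph), seed = 13)
  relCoords <- function(mask) {
    idx <- which(imgData(mask), arr.ind = TRUE)
    idx <- sweep(idx, 2, apply(idx, 2, min))
    idx[order(idx[, 1], idx[, 2], idx[, 3]), ]
  }
  ref <- relCoords(tumor)
  lv <- radUnique:::phantomLabelLevels()
  for (tg in names(pls)) {
    pl <- pls[[tg]]
    expect_identical(voxelCount(pl@mask), voxelCount(tumor))
    expect_identical(relCoords(pl@mask), ref)
    # 100% containment in the target tissue
    expect_true(all(tissueLabels(ph)[imgData(pl@mask)] == lv[[tg]]))
  }
})

test_that("placement choice is deterministic under a fixed seed", {
  ph <- generatePhantom(PhantomSpec(dims = c(16, 40, 40), noduleDiameter = 6,
                                    seed = 1L))
  a <- findPlacements(noduleMask(ph), tissueLabels(ph), seed = 5)
  b <- findPlacements(noduleMask(ph), tissueLabels(ph), seed = 5)
  for (tg in names(a)) expect_identical(a[[tg]]@offset, b[[tg]]@offset)
})

test_that("degenerate inputs are rejected or reported", {
  d <- c(3, 5, 5)
  empty <- RoiMask(array(FALSE, d))
  expect_error(findPlacements(empty, gridLabels(d), targets = "t",
                              tissueLevels = c(t = 1L)), "empty")
  m <- array(FALSE, d); m[2, 2:4, 2:4] <- TRUE
  lab <- gridLabels(d)
  lab[1, 1, 1] <- 7L                   # too small for the 3x3 ROI anywhere
  expect_warning(
    out <- findPlacements(RoiMask(m), lab, targets = "tiny",
                          tissueLevels = c(tiny = 7L), seed = 1),
    "unplaceable")
  expect_null(out$tiny)
})
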
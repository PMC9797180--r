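test_that("coefficient of variation matches hand computation", {
  expect_equal(coefficientOfVariation(c(2, 2, 2, 2, 2)), 0)
  expect_equal(coefficientOfVariation(1:5), 100 * sqrt(2.5) / 3)
  expect_equal(round(coefficientOfVariation(1:5), 2), 52.70)
  expect_true(is.na(coefficientOfVariation(c(-1, 1))))   # mean ~ 0
  expect_true(is.na(coefficientOfVariation(c(3))))       # < 2 values
  expect_true(is.na(coefficientOfVariation(c(NA, 4))))
  # scale invariance for k > 0
  set.seed(1)
  v <- rnorm(5, 50, 5)
  expect_equal(coefficientOfVariation(3.7 * v), coefficientOfVariation(v))
})

test_that("Lin's CCC matches hand evaluation and brute force", {
  expect_equal(linCcc(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(linCcc(c(1, 2, 3), c(2, 3, 4)), 4 / 7)
  # anti-concordant series: direct formula oracle
  x <- c(1, 2, 3); y <- c(3, 2, 1)
  direct <- 2 * mean((x - 2) * (y - 2)) /
    (mean((x - 2)^2) + mean((y - 2)^2) + 0)
  expect_equal(linCcc(x, y), direct)
  expect_lte(abs(linCcc(x, y)), 1)
  # |CCC| <= |Pearson r| on random pairs
  set.seed(42)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(8) + 0.5 * a
    expect_lte(abs(linCcc(a, b)), abs(cor(a, b)) + 1e-12)
    # invariance under identical permutation of both series
    p <- sample(8)
    expect_equal(linCcc(a[p], b[p]), linCcc(a, b))
  }
  # constant-series conventions
  expect_equal(linCcc(c(2, 2), c(2, 2)), 1)
  expect_equal(linCcc(c(2, 2), c(3, 3)), 0)
  expect_true(is.na(linCcc(1, 2)))
})

# A synthetic patient: tumor values are deterministic; each tissue is a
# transformed copy so CCC behavior is known in advance.
syntheticPatient <- function(pid = "P1", cohort = "GE") {
  exp <- registryExpansion()
  base <- seq_len(nrow(exp)) * 1.7
  vectors <- list(
    tumor = data.frame(exp, value = base),
    adipose = data.frame(exp, value = base),                 # identical
    heart = data.frame(exp, value = base + 5),               # constant shift
    lung = data.frame(exp, value = base * -0.3 + 100),       # anti-scaled
    muscle = data.frame(exp, value = rev(base)))             # scrambled
  patientFeatureTable(pid, cohort, vectors)
}

test_that("identical tumor and tissue vectors give CCC 1 throughout", {
  tbl <- syntheticPatient()
  ccc <- cccTable(tbl)
  adipose <- ccc[ccc$pair == "adipose", ]
  expect_true(all(adipose$ccc == 1, na.rm = TRUE))
  expect_false(any(is.na(adipose$ccc)))
})

test_that("scalar features share one category-level CCC per pair", {
  tbl <- syntheticPatient()
  ccc <- cccTable(tbl)
  gf <- ccc[ccc$pair == "heart" & ccc$category == "IntensityHistGaussFit", ]
  expect_equal(nrow(gf), 6L)
  expect_true(all(gf$mode == "per-category"))
  expect_equal(length(unique(gf$ccc)), 1L)   # the block property
})

test_that("multi-variant features get their own CCC over matched variants", {
  tbl <- syntheticPatient()
  ccc <- cccTable(tbl)
  exp <- registryExpansion()
  idx <- exp$category == "GLCM2D" & exp$feature == "AutoCorrelation"
  x <- (seq_len(nrow(exp)) * 1.7)[idx]
  row <- ccc[ccc$pair == "heart" & ccc$category == "GLCM2D" &
               ccc$feature == "AutoCorrelation", ]
  expect_equal(row$mode, "per-variant")
  expect_equal(row$ccc, linCcc(x, x + 5))
  expect_lt(row$ccc, 1)
})

test_that("per-category grouping mode covers every feature", {
  tbl <- syntheticPatient()
  ccc <- cccTable(tbl, grouping = "category")
  expect_true(all(ccc$mode == "per-category"))
  # all features of one category share the value within a pair
  one <- ccc[ccc$pair == "lung" & ccc$category == "GLCM3D", ]
  expect_equal(length(unique(one$ccc)), 1L)
})

test_that("per-patient CV is the variant-mean CV across the five regions", {
  tbl <- syntheticPatient()
  cv <- cvTable(tbl)
  expect_equal(nrow(cv), 123L)
  # hand-check one scalar feature: its five values across regions
  exp <- registryExpansion()
  base <- seq_len(nrow(exp)) * 1.7
  i <- which(exp$category == "IntensityDirect" & exp$feature == "GlobalMean")
  vals <- c(base[i], base[i], base[i] + 5, base[i] * -0.3 + 100,
            rev(base)[i])
  want <- coefficientOfVariation(vals)
  got <- cv$cv[cv$category == "IntensityDirect" & cv$feature == "GlobalMean"]
  expect_equal(got, want)
})

test_that("undefined feature values are dropped pairwise", {
  tbl <- syntheticPatient()
  tbl$value[tbl$tissue_region == "heart" &
              tbl$category == "GLCM2D"] <- NA_real_
  ccc <- cccTable(tbl)
  heartGlcm <- ccc[ccc$pair == "heart" & ccc$category == "GLCM2D", ]
  expect_true(all(is.na(heartGlcm$ccc)))
  # other pairs unaffected
  expect_false(any(is.na(ccc$ccc[ccc$pair == "adipose"])))
})
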
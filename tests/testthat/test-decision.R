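test_that("the inclusive patient-fraction rule admits exactly half", {
  cfg <- DecisionConfig()
  counts <- data.frame(category = "GLCM2D",
                       feature = c("Energy", "Entropy", "Contrast"),
                       failed = c(9, 8, 10), total = 18)
  v <- cvVerdictsFromCounts(counts, cfg)
  nu <- v$feature[v$nonunique]
  expect_true("Energy" %in% nu)            # 9/18 qualifies inclusively
  expect_false("Entropy" %in% nu)          # 8/18 does not
  strict <- DecisionConfig(inclusiveFraction = FALSE)
  vs <- cvVerdictsFromCounts(counts, strict)
  expect_false("Energy" %in% vs$feature[vs$nonunique])
  expect_true("Contrast" %in% vs$feature[vs$nonunique])
})

test_that("a feature failing exactly one tissue pair stays unique", {
  counts <- data.frame(category = "GrayRunLength2D",
                       feature = c("ShortRunEmphasis", "LongRunEmphasis"),
                       regions_failed = c(1, 2))
  v <- cccVerdictsFromRegionCounts(counts, DecisionConfig())
  expect_false(v$nonunique[v$feature == "ShortRunEmphasis"])
  expect_true(v$nonunique[v$feature == "LongRunEmphasis"])
})

test_that("all-zero counts yield no nonunique features", {
  reg <- featureRegistry()
  v <- cvVerdictsFromCounts(data.frame(category = reg$category[1],
                                       feature = reg$feature[1],
                                       failed = 0, total = 14),
                            DecisionConfig())
  expect_false(any(v$nonunique))
})

randomCv <- function(seed, n = 6) {
  set.seed(seed)
  reg <- featureRegistry()
  do.call(rbind, lapply(seq_len(n), function(k)
    data.frame(patient = sprintf("P%02d", k), cohort = "X",
               category = reg$category, feature = reg$feature,
               cv = runif(nrow(reg), 0, 30))))
}

test_that("verdict sets are monotone in the thresholds", {
  cv <- randomCv(5)
  sets <- lapply(c(5, 10, 20), function(th)
    with(cvVerdicts(cv, 6, DecisionConfig(cvThreshold = th)),
         paste(category, feature)[nonunique]))
  expect_true(all(sets[[1]] %in% sets[[2]]))   # lower CV cut shrinks the set
  expect_true(all(sets[[2]] %in% sets[[3]]))
  fr <- lapply(c(0.5, 0.8), function(f)
    with(cvVerdicts(cv, 6, DecisionConfig(patientFraction = f)),
         paste(category, feature)[nonunique]))
  expect_true(all(fr[[2]] %in% fr[[1]]))       # higher fraction shrinks
})

test_that("the combined set is contained in every cohort set", {
  rep <- replayUniqueness()
  sets <- reportSets(rep)
  for (nm in c("cv_GE", "cv_Siemens", "ccc_GE", "ccc_Siemens"))
    expect_true(all(sets$combined %in% sets[[nm]]), label = nm)
  expect_true(all(sets$combined %in% sets$cv_all_cohorts))
  expect_true(all(sets$combined %in% sets$ccc_all_cohorts))
})

test_that("a single-cohort run combines to the CV/CCC intersection", {
  counts <- loadReplayCounts()
  cfg <- DecisionConfig()
  cvv <- cvVerdictsFromCounts(counts$cv$GE, cfg)
  cccv <- cccVerdictsFromRegionCounts(counts$ccc$GE, cfg)
  rep <- combineVerdicts(list(GE = cvv), list(GE = cccv), cfg)
  sets <- reportSets(rep)
  expect_setequal(sets$combined, intersect(sets$cv_GE, sets$ccc_GE))
})

test_that("the HistArea exclusion flag removes the same-shape artifact", {
  cfg <- DecisionConfig(combineRule = "union", excludeHistArea = TRUE)
  rep <- replayUniqueness(cfg)
  expect_false("IntensityHistGaussFit|HistArea" %in%
                 reportSets(rep)$combined)
})

test_that("raising the CCC patient fraction never enlarges pair failures", {
  # patient-level path: synthetic CCC table over two patients
  set.seed(9)
  reg <- featureRegistry()
  ccc <- do.call(rbind, lapply(sprintf("P%d", 1:4), function(pid)
    do.call(rbind, lapply(radUnique:::tumorPairs(), function(pr)
      data.frame(patient = pid, cohort = "X", pair = pr,
                 category = reg$category, feature = reg$feature,
                 mode = "per-variant",
                 ccc = runif(nrow(reg), 0.5, 1))))))
  a <- cccVerdicts(ccc, 4, DecisionConfig(patientFraction = 0.5))
  b <- cccVerdicts(ccc, 4, DecisionConfig(patientFraction = 0.75))
  expect_true(all(b$regions_failed <= a$regions_failed))
  expect_true(all(paste(b$category, b$feature)[b$nonunique] %in%
                    paste(a$category, a$feature)[a$nonunique]))
})
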
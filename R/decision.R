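#' Construct a DecisionConfig
#'
#' Thresholds and aggregation rules for feature-uniqueness verdicts. The
#' defaults encode the published rule set: a feature is flagged in a patient
#' when CV < 10\% (or CCC > 0.85); flagged in at least 50\% of patients
#' (inclusive) makes it CV-nonunique (or a failure for that tissue pair);
#' failing >= 2 of the 4 tissue pairs makes it CCC-nonunique; and the
#' combined nonunique set is CV-nonunique in every cohort AND CCC-nonunique
#' in every cohort. The inclusive patient-fraction comparison is what
#' reproduces the published per-cohort totals.
#'
#' @param cvThreshold CV percent threshold (default 10).
#' @param cccThreshold CCC threshold (default 0.85).
#' @param patientFraction fraction of patients (default 0.5).
#' @param inclusiveFraction use count >= fraction * n (default TRUE).
#' @param minFailingPairs tissue pairs needed for CCC nonuniqueness
#'   (default 2).
#' @param combineRule "both", "any" or "union" (default "both").
#' @param excludeHistArea drop HistArea (same-shape artifact) from the
#'   combined set (default FALSE).
#' @return a \linkS4class{DecisionConfig}.
#' @export
DecisionConfig <- function(cvThreshold = 10, cccThreshold = 0.85,
                           patientFraction = 0.5, inclusiveFraction = TRUE,
                           minFailingPairs = 2L, combineRule = "both",
                           excludeHistArea = FALSE) {
  new("DecisionConfig", cvThreshold = cvThreshold,
      cccThreshold = cccThreshold, patientFraction = patientFraction,
      inclusiveFraction = inclusiveFraction,
      minFailingPairs = as.integer(minFailingPairs),
      combineRule = combineRule, excludeHistArea = excludeHistArea)
}

meetsFraction <- function(count, total, config) {
  cut <- config@patientFraction * total
  if (config@inclusiveFraction) count >= cut else count > cut
}

featureKey <- function(df) paste(df$category, df$feature, sep = "|")

# Align a (category, feature, ...) data.frame onto the full registry,
# filling absent features with `fill`.
alignToRegistry <- function(df, registry, col, fill = 0) {
  out <- registry[, c("category", "feature")]
  out[[col]] <- fill
  m <- match(featureKey(df), featureKey(out))
  if (anyNA(m)) stop("unknown features: ",
                     paste(featureKey(df)[is.na(m)], collapse = ", "))
  out[[col]][m] <- df[[col]]
  out
}

#' CV verdicts from per-feature flagged-patient counts
#'
#' @param counts data.frame(category, feature, failed, total): number of
#'   patients in which the feature had CV below threshold.
#' @param config \linkS4class{DecisionConfig}.
#' @param registry \code{featureRegistry()}; features absent from
#'   \code{counts} get a zero count.
#' @return data.frame(category, feature, failed, total, nonunique).
#' @export
cvVerdictsFromCounts <- function(counts, config = DecisionConfig(),
                                 registry = featureRegistry()) {
  total <- max(counts$total)
  out <- alignToRegistry(counts, registry, "failed")
  out$total <- total
  out$nonunique <- meetsFraction(out$failed, out$total, config)
  out
}

#' CV verdicts from a computed CV table
#'
#' Counts, per feature, the patients whose CV is defined and below the
#' threshold (undefined CVs never count as flagged), then applies the
#' patient-fraction rule.
#'
#' @param cv output of \code{cvTable} for one cohort.
#' @param nPatients number of patients in the cohort.
#' @param config \linkS4class{DecisionConfig}.
#' @param registry \code{featureRegistry()}.
#' @return data.frame(category, feature, failed, total, nonunique).
#' @export
cvVerdicts <- function(cv, nPatients, config = DecisionConfig(),
                       registry = featureRegistry()) {
  flag <- !is.na(cv$cv) & cv$cv < config@cvThreshold
  agg <- stats::aggregate(flag, by = list(category = cv$category,
                                          feature = cv$feature), FUN = sum)
  names(agg)[3] <- "failed"
  agg$total <- nPatients
  cvVerdictsFromCounts(agg, config, registry)
}

#' CCC verdicts from per-feature failing-region counts
#'
#' @param counts data.frame(category, feature, regions_failed): number of
#'   tissue pairs (0..4) in which the feature failed.
#' @param config \linkS4class{DecisionConfig}.
#' @param registry \code{featureRegistry()}.
#' @return data.frame(category, feature, regions_failed, nonunique).
#' @export
cccVerdictsFromRegionCounts <- function(counts, config = DecisionConfig(),
                                        registry = featureRegistry()) {
  out <- alignToRegistry(counts, registry, "regions_failed")
  out$nonunique <- out$regions_failed >= config@minFailingPairs
  out
}

#' CCC verdicts from a computed CCC table
#'
#' Per (feature, tissue pair), the pair fails when the count of patients
#' with CCC above threshold meets the patient fraction; a feature is
#' nonunique when at least \code{minFailingPairs} pairs fail.
#'
#' @param ccc output of \code{cccTable} for one cohort.
#' @param nPatients number of patients in the cohort.
#' @param config \linkS4class{DecisionConfig}.
#' @param registry \code{featureRegistry()}.
#' @return data.frame(category, feature, regions_failed, nonunique); the
#'   per-pair flagged-patient counts are attached as attribute
#'   \code{"pairCounts"}.
#' @export
cccVerdicts <- function(ccc, nPatients, config = DecisionConfig(),
                        registry = featureRegistry()) {
  flag <- !is.na(ccc$ccc) & ccc$ccc > config@cccThreshold
  per <- stats::aggregate(flag, by = list(category = ccc$category,
                                          feature = ccc$feature,
                                          pair = ccc$pair), FUN = sum)
  names(per)[4] <- "flagged"
  per$total <- nPatients
  per$fails <- meetsFraction(per$flagged, per$total, config)
  agg <- stats::aggregate(per$fails,
                          by = list(category = per$category,
                                    feature = per$feature), FUN = sum)
  names(agg)[3] <- "regions_failed"
  out <- cccVerdictsFromRegionCounts(agg, config, registry)
  attr(out, "pairCounts") <- per
  out
}

#' Combine per-cohort CV and CCC verdicts into a uniqueness report
#'
#' Under the default rule a feature is nonunique overall when it is
#' CV-nonunique in every cohort and CCC-nonunique in every cohort. All
#' intermediate sets (per-cohort CV and CCC sets, their cross-cohort
#' intersections) are exposed in the report.
#'
#' @param cvList named list (by cohort) of CV verdict data.frames.
#' @param cccList named list (by cohort, same names) of CCC verdict
#'   data.frames.
#' @param config \linkS4class{DecisionConfig}.
#' @param registry \code{featureRegistry()}.
#' @return a \linkS4class{UniquenessReport}.
#' @export
combineVerdicts <- function(cvList, cccList, config = DecisionConfig(),
                            registry = featureRegistry()) {
  if (!identical(sort(names(cvList)), sort(names(cccList))))
    stop("cvList and cccList must cover the same cohorts")
  cohorts <- names(cvList)
  regKeys <- featureKey(registry)
  for (co in cohorts) {
    if (!identical(featureKey(cvList[[co]]), regKeys) ||
        !identical(featureKey(cccList[[co]]), regKeys))
      stop("verdict sets must share the registry ordering")
  }
  cvSets <- lapply(cvList, function(v) regKeys[v$nonunique])
  cccSets <- lapply(cccList, function(v) regKeys[v$nonunique])
  cvAll <- Reduce(intersect, cvSets)
  cccAll <- Reduce(intersect, cccSets)
  combined <- switch(config@combineRule,
    both = intersect(cvAll, cccAll),
    union = union(cvAll, cccAll),
    any = Reduce(union, Map(intersect, cvSets, cccSets)))
  if (config@excludeHistArea)
    combined <- setdiff(combined, "IntensityHistGaussFit|HistArea")
  combined <- regKeys[regKeys %in% combined]

  per <- registry[, c("category", "feature")]
  for (co in cohorts) {
    per[[paste0("cv_failed_", co)]] <- cvList[[co]]$failed
    per[[paste0("cv_total_", co)]] <- cvList[[co]]$total
    per[[paste0("cv_nonunique_", co)]] <- cvList[[co]]$nonunique
    per[[paste0("ccc_regions_failed_", co)]] <- cccList[[co]]$regions_failed
    per[[paste0("ccc_nonunique_", co)]] <- cccList[[co]]$nonunique
  }
  per$combined_nonunique <- regKeys %in% combined

  sets <- c(
    stats::setNames(cvSets, paste0("cv_", cohorts)),
    stats::setNames(cccSets, paste0("ccc_", cohorts)),
    list(cv_all_cohorts = cvAll, ccc_all_cohorts = cccAll,
         combined = combined))
  new("UniquenessReport", perFeature = per, sets = sets, config = config,
      cohorts = cohorts)
}

#' Nonunique feature sets of a report
#' @param report a \linkS4class{UniquenessReport}.
#' @return named list of feature-key character vectors.
#' @export
reportSets <- function(report) report@sets

#' Per-feature verdict table of a report
#' @param report a \linkS4class{UniquenessReport}.
#' @return data.frame, one row per registry feature.
#' @export
reportTable <- function(report) report@perFeature

#' Write a uniqueness report
#'
#' One CSV row per feature with all counts and verdicts, plus a JSON summary
#' of set sizes and the configuration.
#'
#' @param report a \linkS4class{UniquenessReport}.
#' @param csvPath output CSV path.
#' @param jsonPath optional JSON summary path.
#' @return invisibly, \code{csvPath}.
#' @export
writeReport <- function(report, csvPath, jsonPath = NULL) {
  utils::write.csv(report@perFeature, csvPath, row.names = FALSE)
  if (!is.null(jsonPath)) {
    cfg <- report@config
    summary <- list(
      set_sizes = lapply(report@sets, length),
      nonunique_pct = round(100 * length(report@sets$combined) /
                              nrow(report@perFeature), 1),
      config = list(cvThreshold = cfg@cvThreshold,
                    cccThreshold = cfg@cccThreshold,
                    patientFraction = cfg@patientFraction,
                    inclusiveFraction = cfg@inclusiveFraction,
                    minFailingPairs = cfg@minFailingPairs,
                    combineRule = cfg@combineRule,
                    excludeHistArea = cfg@excludeHistArea))
    jsonlite::write_json(summary, jsonPath, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(csvPath)
}

#' Load the packaged published per-feature counts
#'
#' Reads the replay fixtures shipped under \code{inst/extdata}: per-cohort
#' CV flagged-patient counts and CCC failing-region counts for the GE
#' (n = 14) and Siemens (n = 18) cohorts. Features not listed in the tables
#' carry a zero count.
#'
#' @return list with elements \code{cv} and \code{ccc}, each a named list of
#'   per-cohort data.frames.
#' @export
loadReplayCounts <- function() {
  p1 <- system.file("extdata", "table1_cv_counts.csv", package = "radUnique")
  p2 <- system.file("extdata", "table2_ccc_counts.csv", package = "radUnique")
  t1 <- utils::read.csv(p1, stringsAsFactors = FALSE)
  t2 <- utils::read.csv(p2, stringsAsFactors = FALSE)
  cv <- lapply(split(t1, t1$cohort), function(df)
    df[!is.na(df$failed), c("category", "feature", "failed", "total")])
  ccc <- lapply(split(t2, t2$cohort), function(df)
    df[!is.na(df$regions_failed),
       c("category", "feature", "regions_failed")])
  list(cv = cv, ccc = ccc)
}

#' Replay the published counts through the decision engine
#'
#' Feeds the packaged per-feature counts into the verdict and combination
#' rules and returns the resulting report. With the default configuration
#' this reproduces the published per-cohort and combined nonunique sets.
#'
#' @param config \linkS4class{DecisionConfig}.
#' @param registry \code{featureRegistry()}.
#' @return a \linkS4class{UniquenessReport}.
#' @export
replayUniqueness <- function(config = DecisionConfig(),
                             registry = featureRegistry()) {
  counts <- loadReplayCounts()
  cvList <- lapply(counts$cv, cvVerdictsFromCounts, config = config,
                   registry = registry)
  cccList <- lapply(counts$ccc, cccVerdictsFromRegionCounts, config = config,
                    registry = registry)
  combineVerdicts(cvList, cccList, config, registry)
}
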
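#' Coefficient of variation in percent
#'
#' 100 * sample standard deviation (n-1 denominator) / |mean|. A zero-variance
#' series has CV 0; when the mean is negligible relative to the spread
#' (|mean| < 1e-9 * sd) the ratio is meaningless and NA is returned.
#'
#' @param values numeric vector; needs >= 2 defined values.
#' @return CV in percent, or NA when undefined.
#' @export
coefficientOfVariation <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) return(NA_real_)
  s <- stats::sd(v)
  if (s == 0) return(0)
  m <- abs(mean(v))
  if (m < 1e-9 * s) return(NA_real_)
  100 * s / m
}

#' Lin's concordance correlation coefficient
#'
#' 2 * s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2) with biased
#' (n-denominator) moments, per Lin's estimator. Two identical constant
#' series are perfectly concordant (1); two unequal constant series carry no
#' agreement information and return 0.
#'
#' @param x,y numeric vectors of equal length; NA pairs are dropped.
#' @return CCC in [-1, 1], or NA with fewer than 2 usable pairs.
#' @export
linCcc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  den <- sx2 + sy2 + (mx - my)^2
  if (den == 0) return(1)            # identical constant series
  2 * sxy / den
}

# Standard tissue order for the five placements and the four tumor pairs.
tissueRegions <- function() c("tumor", "adipose", "heart", "lung", "muscle")
tumorPairs <- function() c("adipose", "heart", "lung", "muscle")

#' Assemble a patient feature table
#'
#' Long-format table of one patient's five ROI extractions.
#'
#' @param patient patient id.
#' @param cohort cohort id.
#' @param vectors named list of \code{extractFeatures} outputs, one per
#'   tissue region in \code{tissueRegions()}.
#' @return data.frame(patient, cohort, tissue_region, category, feature,
#'   variant, value).
#' @export
patientFeatureTable <- function(patient, cohort, vectors) {
  miss <- setdiff(tissueRegions(), names(vectors))
  if (length(miss))
    stop("missing tissue regions: ", paste(miss, collapse = ", "))
  rows <- lapply(tissueRegions(), function(tr) {
    df <- vectors[[tr]]
    data.frame(patient = patient, cohort = cohort, tissue_region = tr,
               df, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Wide value matrix (registry-expansion keys x tissue regions) for one
# patient's rows of a long feature table.
patientWide <- function(df, exp) {
  key <- paste(df$category, df$feature, df$variant, sep = "\r")
  ekey <- paste(exp$category, exp$feature, exp$variant, sep = "\r")
  out <- matrix(NA_real_, nrow(exp), length(tissueRegions()),
                dimnames = list(NULL, tissueRegions()))
  for (tr in tissueRegions()) {
    sub <- df$tissue_region == tr
    out[, tr] <- df$value[sub][match(ekey, key[sub])]
  }
  out
}

#' Per-patient CV of every feature across the five placements
#'
#' CV is computed per (feature, variant) across the five tissue ROIs and
#' averaged over the feature's defined variants, giving one CV per feature
#' per patient (the layout of the CV heatmap: features x patients).
#'
#' @param table long feature table covering >= 1 patient with all five
#'   tissue regions (rows from \code{patientFeatureTable}).
#' @param registry \code{featureRegistry()}.
#' @param params \code{extractionParams()}.
#' @return data.frame(patient, cohort, category, feature, cv).
#' @export
cvTable <- function(table, registry = featureRegistry(),
                    params = extractionParams()) {
  exp <- registryExpansion(registry, params)
  out <- list()
  for (pid in unique(table$patient)) {
    sub <- table[table$patient == pid, ]
    wide <- patientWide(sub, exp)
    cvv <- apply(wide, 1, coefficientOfVariation)
    agg <- tapply(cvv, paste(exp$category, exp$feature, sep = "\r"),
                  function(z) if (all(is.na(z))) NA_real_
                              else mean(z, na.rm = TRUE))
    keys <- strsplit(names(agg), "\r", fixed = TRUE)
    out[[pid]] <- data.frame(
      patient = pid, cohort = sub$cohort[1],
      category = vapply(keys, `[`, "", 1),
      feature = vapply(keys, `[`, "", 2),
      cv = unname(as.numeric(agg)), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-patient, per-tissue-pair CCC of every feature
#'
#' For each tumor/tissue pair: a feature with >= 2 variants gets an
#' individual CCC across its variant values (tumor variants vs tissue
#' variants, matched by variant id); single-valued features receive the
#' category-level CCC computed across the scalar features of their category,
#' the same value assigned to every scalar member (so scalar families fail
#' or pass as blocks). With \code{grouping = "category"} every feature uses
#' the category-level CCC over all values of the category.
#'
#' @param table long feature table (rows from \code{patientFeatureTable}).
#' @param registry \code{featureRegistry()}.
#' @param params \code{extractionParams()}.
#' @param grouping "mixed" (default, per-variant for multi-variant features)
#'   or "category".
#' @return data.frame(patient, cohort, pair, category, feature, mode, ccc).
#' @export
cccTable <- function(table, registry = featureRegistry(),
                     params = extractionParams(),
                     grouping = c("mixed", "category")) {
  grouping <- match.arg(grouping)
  exp <- registryExpansion(registry, params)
  featKey <- paste(exp$category, exp$feature, sep = "\r")
  nPerFeat <- table(featKey)
  scalarKeys <- names(nPerFeat)[nPerFeat == 1L]
  out <- list()
  for (pid in unique(table$patient)) {
    sub <- table[table$patient == pid, ]
    wide <- patientWide(sub, exp)
    for (pair in tumorPairs()) {
      xs <- wide[, "tumor"]; ys <- wide[, pair]
      res <- data.frame(category = registry$category,
                        feature = registry$feature,
                        mode = NA_character_, ccc = NA_real_,
                        stringsAsFactors = FALSE)
      catCcc <- new.env()
      for (r in seq_len(nrow(res))) {
        fk <- paste(res$category[r], res$feature[r], sep = "\r")
        if (grouping == "mixed" && nPerFeat[[fk]] >= 2L) {
          idx <- featKey == fk
          res$mode[r] <- "per-variant"
          res$ccc[r] <- linCcc(xs[idx], ys[idx])
        } else {
          ct <- res$category[r]
          if (is.null(catCcc[[ct]])) {
            scal <- if (grouping == "mixed")
              featKey %in% scalarKeys & exp$category == ct
            else exp$category == ct
            catCcc[[ct]] <- linCcc(xs[scal], ys[scal])
          }
          res$mode[r] <- "per-category"
          res$ccc[r] <- catCcc[[ct]]
        }
      }
      res$patient <- pid
      res$cohort <- sub$cohort[1]
      res$pair <- pair
      out[[paste(pid, pair)]] <-
        res[, c("patient", "cohort", "pair", "category", "feature", "mode",
                "ccc")]
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export a CV table as a features-by-patients CSV matrix
#'
#' @param cv output of \code{cvTable}.
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeCvMatrix <- function(cv, path) {
  pats <- unique(cv$patient)
  keys <- unique(paste(cv$category, cv$feature, sep = "|"))
  m <- matrix(NA_real_, length(keys), length(pats),
              dimnames = list(keys, pats))
  m[cbind(match(paste(cv$category, cv$feature, sep = "|"), keys),
          match(cv$patient, pats))] <- cv$cv
  utils::write.csv(data.frame(feature = rownames(m), m, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export a CCC table as a features-by-(pair, patient) CSV matrix
#'
#' @param ccc output of \code{cccTable}.
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeCccMatrix <- function(ccc, path) {
  cols <- unique(paste(ccc$pair, ccc$patient, sep = ":"))
  keys <- unique(paste(ccc$category, ccc$feature, sep = "|"))
  m <- matrix(NA_real_, length(keys), length(cols),
              dimnames = list(keys, cols))
  m[cbind(match(paste(ccc$category, ccc$feature, sep = "|"), keys),
          match(paste(ccc$pair, ccc$patient, sep = ":"), cols))] <- ccc$ccc
  utils::write.csv(data.frame(feature = rownames(m), m, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
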
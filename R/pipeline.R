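#' Build a pipeline run configuration
#'
#' In phantom mode each cohort is a number of synthetic patients with a
#' nodule-diameter range; per-patient sub-seeds are derived by a stable hash
#' of (master seed, patient id) so results do not depend on patient order.
#' The default cohorts mirror the study design: two scanner cohorts with
#' nodule diameters of 11-31 mm and 4-22 mm.
#'
#' In image mode supply \code{patients}: a named list (by cohort) of lists
#' with elements \code{id}, \code{volume}, \code{tumorMask} and
#' \code{labels} (file paths), plus \code{tissueLevels} naming the label
#' values.
#'
#' @param cohorts named list; each element has \code{n} (patients) and
#'   \code{diameterRange} (mm) for phantom mode.
#' @param dims,spacing phantom grid (see \code{PhantomSpec}).
#' @param params \code{extractionParams()}.
#' @param decision \linkS4class{DecisionConfig}.
#' @param outputDir where CSV artifacts are written.
#' @param seed master seed; recorded in every output.
#' @param writeMasks also write each placement as a NIfTI mask.
#' @param mode "phantom" or "images".
#' @param patients image-mode patient list (see above).
#' @param tissueLevels named label values for image mode.
#' @return a run-configuration list.
#' @export
runConfig <- function(cohorts = list(GE = list(n = 5,
                                               diameterRange = c(11, 31)),
                                     Siemens = list(n = 5,
                                                    diameterRange = c(4, 22))),
                      dims = c(48L, 128L, 128L), spacing = c(1, 1, 1),
                      params = extractionParams(),
                      decision = DecisionConfig(),
                      outputDir = tempfile("radunique_run_"), seed = 1L,
                      writeMasks = FALSE, mode = c("phantom", "images"),
                      patients = NULL,
                      tissueLevels = phantomLabelLevels()) {
  mode <- match.arg(mode)
  if (any(vapply(cohorts, function(co) is.null(co$n) || co$n < 1,
                 logical(1))) && mode == "phantom")
    stop("every cohort needs at least one patient")
  list(cohorts = cohorts, dims = as.integer(dims), spacing = spacing,
       params = params, decision = decision, outputDir = outputDir,
       seed = as.integer(seed), writeMasks = writeMasks, mode = mode,
       patients = patients, tissueLevels = tissueLevels)
}

# Extract the five ROI feature vectors for one patient.
extractPatient <- function(volume, tumorMask, labels, tissueLevels, pid,
                           params, seed) {
  placements <- findPlacements(tumorMask, labels, tumorPairs(),
                               tissueLevels = tissueLevels, seed = seed)
  vectors <- list(tumor = extractFeatures(volume, tumorMask,
                                          params = params))
  exp <- registryExpansion(featureRegistry(), params)
  for (tg in tumorPairs()) {
    pl <- placements[[tg]]
    if (is.null(pl)) {
      warning("patient ", pid, ": tissue '", tg,
              "' unplaceable; excluded from its pair statistics")
      vectors[[tg]] <- data.frame(exp, value = NA_real_)
    } else {
      vectors[[tg]] <- extractFeatures(volume, pl@mask, params = params)
    }
  }
  list(vectors = vectors, placements = placements)
}

#' Run the full uniqueness pipeline
#'
#' Phantom generation (or image ingestion), ROI translocation, feature
#' extraction, CV/CCC statistics and the uniqueness decision, with all CSV
#' artifacts written to the output directory: per-cohort long feature tables
#' and placement logs, CV and CCC heatmap matrices, the per-feature report
#' and a JSON summary. A rerun with an identical configuration and seed is
#' bit-identical on every CSV output.
#'
#' @param config output of \code{runConfig()}.
#' @return the \linkS4class{UniquenessReport}; the output directory is
#'   attached as attribute \code{"outputDir"}.
#' @export
runPipeline <- function(config) {
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  registry <- featureRegistry()
  tables <- list()
  cvList <- cccList <- list()
  nPat <- list()

  for (co in names(config$cohorts)) {
    rows <- list()
    logs <- list()
    if (config$mode == "phantom") {
      n <- config$cohorts[[co]]$n
      dr <- config$cohorts[[co]]$diameterRange
      ids <- sprintf("%s%02d", co, seq_len(n))
    } else {
      ids <- vapply(config$patients[[co]], `[[`, "", "id")
      n <- length(ids)
    }
    for (k in seq_along(ids)) {
      pid <- ids[k]
      sub <- stableSubSeed(config$seed, pid)
      if (config$mode == "phantom") {
        diam <- withSeed(sub, stats::runif(1, dr[1], dr[2]))
        spec <- PhantomSpec(dims = config$dims, spacing = config$spacing,
                            noduleDiameter = diam,
                            seed = (sub + 1L) %% 2147483647L)
        ph <- generatePhantom(spec)
        volume <- ph@volume
        tumor <- ph@noduleMask
        labels <- ph@labels
        levels <- ph@tissueLevels
      } else {
        p <- config$patients[[co]][[k]]
        volume <- readVolume(p$volume)
        tumor <- readMask(p$tumorMask, volume)
        labels <- array(as.integer(readVolume(p$labels)@data),
                        dim = dim(volume@data))
        levels <- config$tissueLevels
      }
      ex <- extractPatient(volume, tumor, labels, levels, pid,
                           config$params, seed = (sub + 2L) %% 2147483647L)
      rows[[pid]] <- patientFeatureTable(pid, co, ex$vectors)
      logs[[paste(pid, "tumor")]] <- data.frame(
        patient = pid, tissue = "tumor", dz = 0L, dy = 0L, dx = 0L,
        voxels = voxelCount(tumor), z_fallback = FALSE, seed = sub)
      for (tg in names(ex$placements)) {
        pl <- ex$placements[[tg]]
        logs[[paste(pid, tg)]] <- data.frame(
          patient = pid, tissue = tg,
          dz = if (is.null(pl)) NA_integer_ else pl@offset[1],
          dy = if (is.null(pl)) NA_integer_ else pl@offset[2],
          dx = if (is.null(pl)) NA_integer_ else pl@offset[3],
          voxels = if (is.null(pl)) 0L else voxelCount(pl@mask),
          z_fallback = if (is.null(pl)) NA else pl@usedZFallback,
          seed = sub)
        if (config$writeMasks && !is.null(pl))
          writeMask(pl@mask, file.path(config$outputDir,
                                       sprintf("%s_roi_%s.nii.gz", pid, tg)))
      }
    }
    tbl <- do.call(rbind, rows)
    tables[[co]] <- tbl
    writeFeatureTable(tbl, file.path(config$outputDir,
                                     sprintf("features_%s.csv", co)),
                      overwrite = TRUE)
    utils::write.csv(do.call(rbind, logs),
                     file.path(config$outputDir,
                               sprintf("placements_%s.csv", co)),
                     row.names = FALSE)
    cv <- cvTable(tbl, registry, config$params)
    ccc <- cccTable(tbl, registry, config$params)
    writeCvMatrix(cv, file.path(config$outputDir,
                                sprintf("cv_matrix_%s.csv", co)))
    writeCccMatrix(ccc, file.path(config$outputDir,
                                  sprintf("ccc_matrix_%s.csv", co)))
    cvList[[co]] <- cvVerdicts(cv, n, config$decision, registry)
    cccList[[co]] <- cccVerdicts(ccc, n, config$decision, registry)
    nPat[[co]] <- n
  }

  report <- combineVerdicts(cvList, cccList, config$decision, registry)
  writeReport(report, file.path(config$outputDir, "report.csv"),
              file.path(config$outputDir, "summary.json"))
  attr(report, "outputDir") <- config$outputDir
  attr(report, "featureTables") <- tables
  report
}
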
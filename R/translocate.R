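#' Translocate the tumor ROI into other tissue regions
#'
#' For each target tissue the tumor ROI is translated rigidly (no rotation or
#' scaling) so that every foreground voxel lands inside the target tissue
#' label. In-plane positions (zero slice offset) are preferred; only when no
#' in-plane position fully contains the ROI is the search widened to slice
#' offsets of growing magnitude (|dz| = 1, 2, ...). Among all valid positions
#' in the first non-empty group, one is drawn uniformly at random under the
#' seed. Containment is evaluated for all candidate positions at once via an
#' FFT cross-correlation of the target-label indicator with the ROI shape.
#'
#' @param tumor the tumor \linkS4class{RoiMask} (non-empty).
#' @param labels integer 3D tissue-label array congruent with the mask grid.
#' @param targets character vector of target tissue names.
#' @param tissueLevels named integer vector mapping tissue name to label
#'   value (default \code{phantomLabelLevels()}).
#' @param seed integer seed for the random choice among valid positions.
#' @return named list (one entry per target) of \linkS4class{Placement}
#'   objects; an unplaceable tissue yields \code{NULL} with a warning.
#' @export
findPlacements <- function(tumor, labels,
                           targets = c("adipose", "heart", "lung", "muscle"),
                           tissueLevels = phantomLabelLevels(), seed = 1L) {
  if (!identical(dim(labels), dim(tumor@data)))
    stop("label map must be congruent with the tumor mask grid")
  if (length(targets) == 0L) stop("targets must be non-empty")
  coords <- which(tumor@data, arr.ind = TRUE)
  nvox <- nrow(coords)
  if (nvox == 0L) stop("tumor mask is empty")

  minc <- apply(coords, 2, min)
  rel <- sweep(coords, 2, minc)              # 0-based shape coordinates
  sdim <- apply(rel, 2, max) + 1L
  S <- array(FALSE, dim = sdim)
  S[rel + 1L] <- TRUE

  d <- dim(labels)
  P <- d + sdim
  Sp <- array(0, dim = P)
  Sp[seq_len(sdim[1]), seq_len(sdim[2]), seq_len(sdim[3])] <- S
  FS <- stats::fft(Sp)

  out <- vector("list", length(targets))
  names(out) <- targets
  withSeed(seed, {
    for (tg in targets) {
      if (!tg %in% names(tissueLevels))
        stop("unknown tissue: ", tg)
      Tg <- array(0, dim = P)
      Tg[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <-
        as.numeric(labels == tissueLevels[[tg]])
      C <- Re(stats::fft(stats::fft(Tg) * Conj(FS), inverse = TRUE)) / prod(P)
      # valid base corners: full containment, in bounds
      nb <- d - sdim + 1L
      if (any(nb < 1L)) { out[[tg]] <- NULL; next }
      Cb <- C[seq_len(nb[1]), seq_len(nb[2]), seq_len(nb[3]), drop = FALSE]
      valid <- which(Cb > nvox - 0.5, arr.ind = TRUE)
      if (nrow(valid) == 0L) {
        warning("tissue '", tg, "' is unplaceable for this ROI")
        out[tg] <- list(NULL)
        next
      }
      dz <- valid[, 1] - minc[1]
      grp <- abs(dz)
      gmin <- min(grp)
      cand <- valid[grp == gmin, , drop = FALSE]
      pick <- cand[sample.int(nrow(cand), 1L), ]
      offset <- as.integer(pick - minc)
      newmask <- array(FALSE, dim = d)
      newmask[sweep(coords, 2, offset, "+")] <- TRUE
      out[[tg]] <- new("Placement", tissue = tg, offset = offset,
                       mask = new("RoiMask", data = newmask,
                                  spacing = tumor@spacing),
                       usedZFallback = gmin > 0,
                       nCandidates = nrow(cand))
    }
  })
  out
}

#' Write placements and a placement log
#'
#' Saves each placement mask as a NIfTI file named by tissue and a CSV log
#' with the offset, the z-fallback flag, overlap between non-tumor
#' placements, and the seed used.
#'
#' @param placements named list from \code{findPlacements}.
#' @param dir output directory.
#' @param seed the seed that produced the placements (recorded in the log).
#' @return invisibly, the log path.
#' @export
writePlacements <- function(placements, dir, seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (tg in names(placements)) {
    pl <- placements[[tg]]
    if (is.null(pl)) {
      rows[[tg]] <- data.frame(tissue = tg, dz = NA, dy = NA, dx = NA,
                               voxels = 0L, z_fallback = NA,
                               overlaps_other = NA, seed = seed)
      next
    }
    writeMask(pl@mask, file.path(dir, paste0("roi_", tg, ".nii.gz")))
    others <- placements[setdiff(names(placements), tg)]
    ovl <- any(vapply(others, function(o) {
      !is.null(o) && any(o@mask@data & pl@mask@data)
    }, logical(1)))
    rows[[tg]] <- data.frame(tissue = tg, dz = pl@offset[1], dy = pl@offset[2],
                             dx = pl@offset[3], voxels = voxelCount(pl@mask),
                             z_fallback = pl@usedZFallback,
                             overlaps_other = ovl, seed = seed)
  }
  log <- do.call(rbind, rows)
  path <- file.path(dir, "placements.csv")
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}
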
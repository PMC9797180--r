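#' Specify a synthetic CT phantom
#'
#' Builds a \linkS4class{PhantomSpec} with textbook attenuation defaults:
#' lung -800 HU, adipose -100 HU, heart +40 HU, muscle +50 HU, nodule +20 HU.
#' Texture is modeled per tissue as Gaussian white noise smoothed with a
#' Gaussian kernel of the given correlation length, standardized within the
#' tissue region and added to the tissue mean, so each region has exactly the
#' requested mean and standard deviation.
#'
#' @param dims integer(3) grid size (slice, row, column), each >= 16.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param tissues data.frame with columns tissue, meanHU, noiseSd, corLength
#'   covering lung, adipose, heart, muscle, nodule.
#' @param noduleDiameter nodule diameter in mm (must fit in the lung slab).
#' @param rimDrop HU decrease from nodule center to rim (mean-centered radial
#'   ramp); 0 disables the gradient.
#' @param seed integer seed; identical spec + seed gives bit-identical output.
#' @return a \linkS4class{PhantomSpec}.
#' @examples
#' spec <- PhantomSpec(dims = c(24, 64, 64), noduleDiameter = 10, seed = 7)
#' ph <- generatePhantom(spec)
#' voxelCount(noduleMask(ph))
#' @export
PhantomSpec <- function(dims = c(48L, 128L, 128L), spacing = c(1, 1, 1),
                        tissues = defaultTissues(), noduleDiameter = 16,
                        rimDrop = 30, seed = 1L) {
  new("PhantomSpec", dims = as.integer(dims), spacing = as.numeric(spacing),
      tissues = tissues, noduleDiameter = as.numeric(noduleDiameter),
      rimDrop = as.numeric(rimDrop), seed = as.integer(seed))
}

#' Default tissue attenuation and texture parameters
#'
#' Means follow textbook CT attenuation ranges; noise levels and correlation
#' lengths are free knobs chosen to give the five classes distinct first- and
#' second-order statistics.
#'
#' @return data.frame with columns tissue, meanHU, noiseSd, corLength.
#' @export
defaultTissues <- function() {
  data.frame(
    tissue    = c("lung", "adipose", "heart", "muscle", "nodule"),
    meanHU    = c(-800,   -100,       40,      50,       20),
    noiseSd   = c(40,      15,        20,      18,       30),
    corLength = c(2,       2,         2,       1.5,      1.5),
    stringsAsFactors = FALSE
  )
}

# Separable Gaussian smoothing of a 3D array, zero-padded and renormalized by
# the smoothed indicator so edges are unbiased.
gaussSmooth3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  smoothAxis <- function(x, d1) {
    m <- matrix(x, d1)
    mp <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
    f <- stats::filter(mp, k, sides = 2)
    as.numeric(f[(r + 1):(r + d1), , drop = FALSE])
  }
  d <- dim(a)
  pass <- function(a) {
    a <- array(smoothAxis(a, d[1]), dim = d)
    b <- aperm(a, c(2, 1, 3))
    b <- array(smoothAxis(b, d[2]), dim = d[c(2, 1, 3)])
    a <- aperm(b, c(2, 1, 3))
    b <- aperm(a, c(3, 1, 2))
    b <- array(smoothAxis(b, d[3]), dim = d[c(3, 1, 2)])
    aperm(b, c(2, 3, 1))
  }
  env <- pass(array(1, dim = d))     # edge attenuation envelope
  pass(a) / env
}

# Tissue label values used by the slab phantom.
phantomLabelLevels <- function() {
  c(lung = 1L, adipose = 2L, heart = 3L, muscle = 4L, nodule = 5L)
}

#' Generate a deterministic labeled phantom
#'
#' Lays out four tissue slabs along the row axis (adipose, heart, muscle,
#' lung) spanning all slices and columns, embeds a spherical nodule at the
#' center of the lung slab, and adds per-tissue correlated Gaussian texture.
#' Output is a pure function of the spec (including its seed).
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return a \linkS4class{LabeledPhantom}.
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  d <- spec@dims
  sp <- spec@spacing
  lv <- phantomLabelLevels()
  tt <- spec@tissues

  # four equal tissue slabs along the row axis: every slab must be able to
  # host the translocated nodule, so equal quarters maximize the minimum
  b <- floor(d[2] / 4)
  rowIdx <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
  labels <- array(0L, dim = d)
  labels[rowIdx <= b] <- lv[["adipose"]]
  labels[rowIdx > b & rowIdx <= 2 * b] <- lv[["heart"]]
  labels[rowIdx > 2 * b & rowIdx <= 3 * b] <- lv[["muscle"]]
  labels[rowIdx > 3 * b] <- lv[["lung"]]

  # nodule sphere centered in the lung slab
  ctr <- c((1 + d[1]) / 2, (3 * b + 1 + d[2]) / 2, (1 + d[3]) / 2)
  R <- spec@noduleDiameter / 2
  ax1 <- ((seq_len(d[1]) - ctr[1]) * sp[1])^2
  ax2 <- ((seq_len(d[2]) - ctr[2]) * sp[2])^2
  ax3 <- ((seq_len(d[3]) - ctr[3]) * sp[3])^2
  dist2 <- outer(outer(ax1, ax2, "+"), ax3, "+")
  sphere <- dist2 <= R^2
  if (!all(labels[sphere] == lv[["lung"]]))
    stop("nodule does not fit inside the lung region")
  labels[sphere] <- lv[["nodule"]]

  vol <- array(0, dim = d)
  for (i in seq_len(nrow(tt))) {
    reg <- labels == lv[[tt$tissue[i]]]
    vol[reg] <- tt$meanHU[i]
  }

  withSeed(spec@seed, {
    for (i in seq_len(nrow(tt))) {
      sdv <- tt$noiseSd[i]
      reg <- labels == lv[[tt$tissue[i]]]
      if (sdv <= 0 || !any(reg)) next
      noise <- gaussSmooth3(array(stats::rnorm(prod(d)), dim = d),
                            tt$corLength[i])
      z <- noise[reg]
      z <- (z - mean(z)) / stats::sd(z)     # exact region mean and sd
      vol[reg] <- vol[reg] + sdv * z
    }
  })

  if (spec@rimDrop != 0) {
    rel <- sqrt(dist2[sphere]) / R          # 0 at center, 1 at rim
    vol[sphere] <- vol[sphere] - spec@rimDrop * (rel - mean(rel))
  }

  new("LabeledPhantom",
      volume = ImageVolume(vol, spacing = sp),
      labels = labels, tissueLevels = lv,
      noduleMask = RoiMask(sphere, spacing = sp))
}

#' Nodule mask accessor
#' @param x a \linkS4class{LabeledPhantom}.
#' @return the nodule \linkS4class{RoiMask}.
#' @export
noduleMask <- function(x) x@noduleMask

#' Tissue label map accessor
#' @param x a \linkS4class{LabeledPhantom}.
#' @return integer 3D array of tissue labels.
#' @export
tissueLabels <- function(x) x@labels

#' Phantom volume accessor
#' @param x a \linkS4class{LabeledPhantom}.
#' @return the \linkS4class{ImageVolume}.
#' @export
phantomVolume <- function(x) x@volume

#' Write a phantom to disk
#'
#' Writes volume, label map and nodule mask as NIfTI plus the spec as a
#' plain-text key = value config recording the seed.
#'
#' @param phantom a \linkS4class{LabeledPhantom}.
#' @param spec the \linkS4class{PhantomSpec} that produced it.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writePhantom <- function(phantom, spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pv <- file.path(dir, "volume.nii.gz")
  pl <- file.path(dir, "labels.nii.gz")
  pm <- file.path(dir, "nodule_mask.nii.gz")
  pc <- file.path(dir, "phantom_spec.txt")
  writeVolume(phantom@volume, pv)
  writeVolume(ImageVolume(phantom@labels + 0, spacing = spec@spacing), pl)
  writeMask(phantom@noduleMask, pm)
  tt <- spec@tissues
  lines <- c(
    sprintf("dims = %s", paste(spec@dims, collapse = " ")),
    sprintf("spacing = %s", paste(spec@spacing, collapse = " ")),
    sprintf("noduleDiameter = %g", spec@noduleDiameter),
    sprintf("rimDrop = %g", spec@rimDrop),
    sprintf("seed = %d", spec@seed),
    sprintf("tissue %s meanHU=%g noiseSd=%g corLength=%g",
            tt$tissue, tt$meanHU, tt$noiseSd, tt$corLength))
  writeLines(lines, pc)
  invisible(c(pv, pl, pm, pc))
}
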
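#' @import methods
NULL

#' ImageVolume: a 3D scalar CT volume
#'
#' Container for a 3D scalar field in Hounsfield units (HU) together with its
#' voxel spacing and origin. The internal axis convention is (slice, row,
#' column): the first array dimension indexes axial slices, so "in-plane"
#' operations fix the first index.
#'
#' @slot data 3D numeric array of HU values.
#' @slot spacing numeric(3), voxel spacing in mm per (slice, row, column) axis.
#' @slot origin numeric(3), position of voxel (1,1,1) in mm.
#' @export
setClass("ImageVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0)),
  validity = function(object) {
    if (length(dim(object@data)) != 3L)
      return("data must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      return("spacing must be 3 strictly positive finite values")
    if (length(object@origin) != 3L)
      return("origin must have length 3")
    if (any(!is.finite(object@data)))
      return("volume values must be finite")
    TRUE
  }
)

#' RoiMask: a binary region-of-interest mask
#'
#' Binary 3D mask congruent with an \linkS4class{ImageVolume}. Any nonzero
#' voxel of the source data is foreground.
#'
#' @slot data 3D logical array.
#' @slot spacing numeric(3), voxel spacing in mm (slice, row, column).
#' @export
setClass("RoiMask",
  representation(data = "array", spacing = "numeric"),
  prototype(spacing = c(1, 1, 1)),
  validity = function(object) {
    if (length(dim(object@data)) != 3L)
      return("mask must be a 3D array")
    if (!is.logical(object@data))
      return("mask data must be logical")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 strictly positive values")
    TRUE
  }
)

#' PhantomSpec: parameters of the synthetic CT phantom
#'
#' Describes a deterministic synthetic CT volume with five tissue classes
#' (lung, adipose, heart, muscle, nodule). Tissues are laid out as four slabs
#' along the row axis (adipose, heart, muscle, lung), with a spherical nodule
#' embedded in the lung slab; each tissue carries its own mean attenuation,
#' noise standard deviation and spatial correlation length so that texture
#' statistics differ between regions.
#'
#' @slot dims integer(3), grid size in voxels (slice, row, column); each >= 16.
#' @slot spacing numeric(3), voxel spacing in mm.
#' @slot tissues data.frame with columns tissue, meanHU, noiseSd, corLength
#'   for the five classes; mean attenuations must be pairwise distinct.
#' @slot noduleDiameter numeric, nodule diameter in mm; the sphere must fit
#'   inside the lung slab.
#' @slot rimDrop numeric, HU decrease from nodule center to rim (radial
#'   gradient; gives non-degenerate gradient-orientation statistics).
#' @slot seed integer random seed; same spec + seed is bit-identical.
#' @export
setClass("PhantomSpec",
  representation(dims = "integer", spacing = "numeric", tissues = "data.frame",
                 noduleDiameter = "numeric", rimDrop = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (length(object@dims) != 3L || any(object@dims < 16L))
      return("dims must be 3 values, each >= 16 voxels")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be strictly positive")
    tt <- object@tissues
    need <- c("lung", "adipose", "heart", "muscle", "nodule")
    if (!all(need %in% tt$tissue))
      return("tissues must include lung, adipose, heart, muscle, nodule")
    if (anyDuplicated(tt$meanHU))
      return("tissue mean attenuations must be pairwise distinct")
    if (any(tt$noiseSd < 0) || any(tt$corLength < 0))
      return("noiseSd and corLength must be non-negative")
    if (object@noduleDiameter <= 0)
      return("noduleDiameter must be positive")
    dvox <- object@noduleDiameter / object@spacing
    # lung slab = last quarter of the row axis, full slices/columns
    slab <- c(object@dims[1],
              object@dims[2] - 3 * floor(object@dims[2] / 4), object@dims[3])
    if (any(dvox > slab - 1))
      return("nodule does not fit inside the lung slab at this spacing")
    TRUE
  }
)

#' LabeledPhantom: synthetic volume plus tissue labels and nodule mask
#'
#' @slot volume \linkS4class{ImageVolume}.
#' @slot labels 3D integer array of tissue labels congruent with the volume.
#' @slot tissueLevels named integer vector mapping tissue name -> label value
#'   (0 is reserved for background, unused by the slab phantom).
#' @slot noduleMask \linkS4class{RoiMask} for the nodule; a subset of the
#'   nodule label.
#' @export
setClass("LabeledPhantom",
  representation(volume = "ImageVolume", labels = "array",
                 tissueLevels = "integer", noduleMask = "RoiMask"),
  validity = function(object) {
    if (!identical(dim(object@labels), dim(object@volume@data)))
      return("label map and volume must have identical dimensions")
    if (!identical(dim(object@noduleMask@data), dim(object@labels)))
      return("nodule mask must be congruent with the label map")
    lv <- object@tissueLevels
    if (is.null(names(lv)) || !("nodule" %in% names(lv)))
      return("tissueLevels must be named and include 'nodule'")
    if (any(object@noduleMask@data & object@labels != lv[["nodule"]]))
      return("nodule mask must be a subset of the nodule label")
    TRUE
  }
)

#' Placement: one shape-preserved translocation of the tumor ROI
#'
#' @slot tissue character, target tissue label name.
#' @slot offset integer(3), rigid translation in voxels (slice, row, column)
#'   relative to the original tumor ROI.
#' @slot mask \linkS4class{RoiMask} of the translated ROI.
#' @slot usedZFallback logical, TRUE when no in-plane (zero slice offset)
#'   position contained the ROI and a slice shift was required.
#' @slot nCandidates integer, number of valid positions the random choice was
#'   drawn from.
#' @export
setClass("Placement",
  representation(tissue = "character", offset = "integer", mask = "RoiMask",
                 usedZFallback = "logical", nCandidates = "integer"),
  validity = function(object) {
    if (length(object@offset) != 3L) return("offset must have length 3")
    TRUE
  }
)

#' DecisionConfig: thresholds and aggregation rules for uniqueness verdicts
#'
#' @slot cvThreshold numeric, CV percent threshold (default 10): a feature is
#'   flagged in a patient when CV < cvThreshold.
#' @slot cccThreshold numeric, CCC threshold (default 0.85): flagged when
#'   CCC > cccThreshold.
#' @slot patientFraction numeric in (0, 1], fraction of patients required
#'   (default 0.5).
#' @slot inclusiveFraction logical; TRUE (default) counts a feature when
#'   flagged patients >= fraction * n, FALSE requires strictly more.
#' @slot minFailingPairs integer in 1..4, tissue pairs that must fail for CCC
#'   nonuniqueness (default 2).
#' @slot combineRule character, how cohort verdicts combine: "both" (default,
#'   CV-nonunique in every cohort AND CCC-nonunique in every cohort), "any"
#'   (nonunique in any cohort by both metrics), or "union" (CV or CCC in
#'   every cohort).
#' @slot excludeHistArea logical, drop the Gauss-fit HistArea feature from
#'   the combined set (same-shape artifact); default FALSE.
#' @export
setClass("DecisionConfig",
  representation(cvThreshold = "numeric", cccThreshold = "numeric",
                 patientFraction = "numeric", inclusiveFraction = "logical",
                 minFailingPairs = "integer", combineRule = "character",
                 excludeHistArea = "logical"),
  prototype(cvThreshold = 10, cccThreshold = 0.85, patientFraction = 0.5,
            inclusiveFraction = TRUE, minFailingPairs = 2L,
            combineRule = "both", excludeHistArea = FALSE),
  validity = function(object) {
    if (object@cvThreshold <= 0) return("cvThreshold must be positive")
    if (object@cccThreshold <= -1 || object@cccThreshold >= 1)
      return("cccThreshold must lie in (-1, 1)")
    if (object@patientFraction <= 0 || object@patientFraction > 1)
      return("patientFraction must lie in (0, 1]")
    if (object@minFailingPairs < 1L || object@minFailingPairs > 4L)
      return("minFailingPairs must lie in 1..4")
    if (!object@combineRule %in% c("both", "any", "union"))
      return("combineRule must be 'both', 'any' or 'union'")
    TRUE
  }
)

#' UniquenessReport: per-feature verdicts and derived sets
#'
#' @slot perFeature data.frame, one row per registry feature with CV-fail
#'   patient counts, CCC failing-pair counts, per-cohort verdicts and the
#'   combined verdict.
#' @slot sets named list of character vectors (feature keys) for each
#'   intermediate set and the combined nonunique set.
#' @slot config \linkS4class{DecisionConfig} used.
#' @slot cohorts character vector of cohort names in input order.
#' @export
setClass("UniquenessReport",
  representation(perFeature = "data.frame", sets = "list",
                 config = "DecisionConfig", cohorts = "character"))
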
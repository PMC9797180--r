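#' Read a CT volume from NIfTI or a DICOM series directory
#'
#' NIfTI files are read natively. A directory is treated as a DICOM series
#' and converted through the bundled SimpleITK helper script (requires a
#' \code{python} with SimpleITK on the PATH); the DICOM rescale slope and
#' intercept are applied so values are in HU. Mixed-series directories and
#' volumes without spacing metadata are rejected.
#'
#' @param path a NIfTI file (.nii or .nii.gz) or a DICOM series directory.
#' @return an \linkS4class{ImageVolume} with axis order (slice, row, column).
#' @export
readVolume <- function(path) {
  if (dir.exists(path)) {
    script <- system.file("scripts", "dicom_to_nifti.py", package = "radUnique")
    tmp <- tempfile(fileext = ".nii.gz")
    on.exit(unlink(tmp))
    res <- suppressWarnings(
      system2("python", c(shQuote(script), shQuote(path), shQuote(tmp)),
              stdout = TRUE, stderr = TRUE))
    status <- attr(res, "status")
    if (!is.null(status) && status != 0)
      stop("DICOM series read failed: ", paste(res, collapse = "; "))
    path <- tmp
  }
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D volume, got ", length(dim(arr)), " dimensions")
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("volume has missing or non-positive spacing metadata")
  ImageVolume(aperm(arr, c(3, 2, 1)), spacing = rev(sp))
}

#' Write a volume as NIfTI
#'
#' The internal (slice, row, column) array is stored as NIfTI (x = column,
#' y = row, z = slice) so that \code{readVolume} round-trips voxel-identically
#' with spacing preserved.
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param path output .nii or .nii.gz path.
#' @return invisibly, \code{path}.
#' @export
writeVolume <- function(volume, path) {
  img <- RNifti::asNifti(aperm(volume@data, c(3, 2, 1)))
  RNifti::pixdim(img) <- rev(volume@spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary ROI mask congruent with a reference volume
#'
#' Any nonzero stored voxel becomes foreground. The mask grid must match the
#' reference volume exactly.
#'
#' @param path NIfTI mask file.
#' @param reference the \linkS4class{ImageVolume} the mask belongs to.
#' @return an \linkS4class{RoiMask}.
#' @export
readMask <- function(path, reference) {
  v <- readVolume(path)
  if (!identical(dim(v@data), dim(reference@data)))
    stop("mask dimensions ", paste(dim(v@data), collapse = "x"),
         " do not match reference ", paste(dim(reference@data), collapse = "x"))
  RoiMask(v@data != 0, spacing = reference@spacing)
}

#' Write a binary mask as unsigned 8-bit NIfTI
#'
#' @param mask an \linkS4class{RoiMask}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeMask <- function(mask, path) {
  img <- RNifti::asNifti(aperm(array(as.integer(mask@data), dim(mask@data)),
                               c(3, 2, 1)), datatype = "uint8")
  RNifti::pixdim(img) <- rev(mask@spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Apply the DICOM rescale transform
#'
#' HU = stored value * slope + intercept.
#'
#' @param stored numeric stored pixel values.
#' @param slope rescale slope.
#' @param intercept rescale intercept.
#' @return numeric HU values.
#' @export
applyRescale <- function(stored, slope, intercept) stored * slope + intercept

#' Write a long-format feature table as CSV
#'
#' Columns: patient, tissue_region, category, feature, variant, value. Values
#' are written with 17 significant digits so the numeric round trip through
#' \code{readFeatureTable} is lossless at 64-bit precision.
#'
#' @param table data.frame with the columns above (a \code{featureTable}).
#' @param path output CSV path.
#' @param overwrite allow replacing an existing file (default FALSE).
#' @return invisibly, \code{path}.
#' @export
writeFeatureTable <- function(table, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop("file exists: ", path, " (use overwrite = TRUE)")
  need <- c("patient", "tissue_region", "category", "feature", "variant",
            "value")
  if (!all(need %in% names(table)))
    stop("feature table must have columns: ", paste(need, collapse = ", "))
  out <- table[, need, drop = FALSE]
  out$value <- ifelse(is.na(out$value), "", sprintf("%.17g", out$value))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by \code{writeFeatureTable}
#'
#' @param path CSV path.
#' @return data.frame with numeric \code{value} (NA for undefined entries).
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient = "character",
                                       tissue_region = "character",
                                       category = "character",
                                       feature = "character",
                                       variant = "character",
                                       value = "character"))
  df$value <- suppressWarnings(as.numeric(df$value))
  df$variant[is.na(df$variant)] <- ""
  df
}
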
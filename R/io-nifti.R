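#' Read a CT volume from disk
#'
#' Reads either a NIfTI-1 file or a DICOM series directory into a
#' [ct_volume()]. NIfTI is handled by the RNifti library; DICOM series are
#' parsed by a compact reader supporting uncompressed little-endian transfer
#' syntaxes (explicit and implicit VR), which covers standard CT exports.
#'
#' Slice spacing for DICOM is derived from the sorted ImagePositionPatient
#' z-components; gaps deviating from the median by more than `gap_tol`
#' (fraction of the median gap) raise a geometry error naming the offending
#' gap. Missing window tags fall back to `default_window` (lung window) with
#' a message.
#'
#' @param path NIfTI file or DICOM directory.
#' @param format `"auto"`, `"nifti"`, or `"dicom_dir"`.
#' @param default_window `c(WC, WW)` used when the file carries no window
#'   tags. Default `c(-600, 1500)`.
#' @param gap_tol relative tolerance on DICOM slice-gap consistency
#'   (default 0.01 = 1% of the median gap).
#' @return a [ct_volume()]
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom_dir"),
                        default_window = c(-600, 1500), gap_tol = 0.01) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom_dir" else "nifti"
  }
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    assert_that(length(dim(arr)) == 3L, "expected a 3-D NIfTI volume")
    pd <- RNifti::pixdim(img)          # (sx, sy, sz)
    vol <- ct_volume(aperm(arr, c(3, 2, 1)), spacing = rev(pd[1:3]))
    vol$window_center <- default_window[1]
    vol$window_width <- default_window[2]
    vol
  } else {
    read_dicom_series(path, default_window = default_window, gap_tol = gap_tol)
  }
}

#' Write a CT volume as NIfTI
#'
#' @param vol a [ct_volume()]
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  img <- RNifti::asNifti(aperm(vol$data, c(3, 2, 1)))
  RNifti::pixdim(img) <- rev(vol$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a binary mask as uint8 NIfTI
#'
#' @param mask a [mask_volume()]
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mask_volume"))
  img <- RNifti::asNifti(aperm(mask$data, c(3, 2, 1)))
  RNifti::pixdim(img) <- rev(mask$spacing)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' Values are binarised at 0.5 to tolerate masks saved as floats.
#'
#' @param path NIfTI path.
#' @return a [mask_volume()]
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  assert_that(length(dim(arr)) == 3L, "expected a 3-D NIfTI mask")
  pd <- RNifti::pixdim(img)
  mask_volume((aperm(arr, c(3, 2, 1)) > 0.5) * 1L, spacing = rev(pd[1:3]))
}
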
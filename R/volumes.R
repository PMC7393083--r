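#' CT volume container
#'
#' A 3-D intensity grid with physical voxel spacing, indexed `(z, y, x)`
#' with z the slice (axial) axis. Spacing is in millimetres per voxel along
#' each axis. `window_center` / `window_width` carry the DICOM display window
#' (HU) used by [normalize_intensity()].
#'
#' Index convention throughout the package: array storage is 1-based as usual
#' in R, but all ROI/VOI coordinates exposed by the API are 0-based with
#' half-open bounds `[lo, hi)`, which keeps box arithmetic additive.
#'
#' @param data numeric 3-D array `(nz, ny, nx)`.
#' @param spacing numeric length-3 `(sz, sy, sx)` in mm, all positive.
#' @param origin numeric length-3 `(oz, oy, ox)` in mm.
#' @param window_center,window_width display window in HU, or `NULL` when
#'   unknown (I/O falls back to a configurable lung window).
#' @return object of class `ct_volume`.
#' @seealso [mask_volume()], [read_volume()], [normalize_intensity()]
#' @export
ct_volume <- function(data, spacing, origin = c(0, 0, 0),
                      window_center = NULL, window_width = NULL) {
  data <- as.array(data)
  assert_that(length(dim(data)) == 3L && all(dim(data) >= 1L),
              "volume data must be a 3-D array with every dimension >= 1")
  spacing <- as.numeric(spacing)
  assert_that(length(spacing) == 3L && all(is.finite(spacing)) && all(spacing > 0),
              "spacing must be three positive numbers (sz, sy, sx) in mm")
  if (!is.null(window_width)) {
    assert_that(window_width > 0, "window_width must be > 0")
  }
  structure(list(
    data = data,
    spacing = spacing,
    origin = as.numeric(origin),
    window_center = window_center,
    window_width = window_width
  ), class = "ct_volume")
}

#' Binary mask volume aligned to a CT grid
#'
#' @param data 3-D array of 0/1 (logical or numeric).
#' @param spacing numeric length-3 `(sz, sy, sx)` in mm.
#' @return object of class `mask_volume`; `data` is stored as integer 0/1.
#' @export
mask_volume <- function(data, spacing) {
  data <- as.array(data)
  assert_that(length(dim(data)) == 3L,
              "mask data must be a 3-D array")
  storage.mode(data) <- "integer"
  assert_that(all(data %in% c(0L, 1L)), "mask values must be 0 or 1")
  spacing <- as.numeric(spacing)
  assert_that(length(spacing) == 3L && all(spacing > 0),
              "spacing must be three positive numbers")
  structure(list(data = data, spacing = spacing), class = "mask_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels (z,y,x), spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  if (!is.null(x$window_center)) {
    cat(sprintf("  window: WC %g, WW %g\n", x$window_center, x$window_width))
  }
  cat(sprintf("  intensity range: [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.mask_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mask_volume> %d x %d x %d voxels, %d foreground (%.3g mm^3)\n",
              d[1], d[2], d[3], sum(x$data), sum(x$data) * prod(x$spacing)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

#' @export
dim.mask_volume <- function(x) dim(x$data)

# voxel volume in mm^3
voxel_volume <- function(x) prod(x$spacing)

check_aligned <- function(a, b) {
  assert_that(identical(dim(a$data), dim(b$data)),
              "mask/volume shapes do not match")
  assert_that(isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-6)),
              "mask/volume spacings do not match")
  invisible(TRUE)
}
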
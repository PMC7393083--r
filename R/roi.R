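#' Square ROI on one axial slice
#'
#' Coordinates are 0-based, half-open: the ROI covers columns `[x1, x2)` and
#' rows `[y1, y2)` of slice `slice`. The ROI is always square
#' (`x2 - x1 == y2 - y1`).
#'
#' @param slice 0-based axial slice index.
#' @param x1,y1 0-based low corner (x = column, y = row).
#' @param side side length in voxels (> 0).
#' @return object of class `square_roi` with fields
#'   `slice, x1, x2, y1, y2`.
#' @export
square_roi <- function(slice, x1, y1, side) {
  side <- as.integer(side)
  assert_that(side > 0, "ROI side must be positive")
  structure(list(slice = as.integer(slice),
                 x1 = as.integer(x1), x2 = as.integer(x1) + side,
                 y1 = as.integer(y1), y2 = as.integer(y1) + side),
            class = "square_roi")
}

roi_side <- function(roi) roi$x2 - roi$x1

#' @export
print.square_roi <- function(x, ...) {
  cat(sprintf("<square_roi> slice %d, x [%d,%d), y [%d,%d), side %d\n",
              x$slice, x$x1, x$x2, x$y1, x$y2, roi_side(x)))
  invisible(x)
}

# translate the ROI into [0, extent) without changing its side; if the side
# exceeds the image it is shrunk to fit (flagged as clamped)
clamp_roi <- function(roi, image_extent) {
  ny <- image_extent[1]; nx <- image_extent[2]
  side <- roi_side(roi)
  clamped <- FALSE
  if (side > min(ny, nx)) {
    side <- as.integer(min(ny, nx))
    cx <- (roi$x1 + roi$x2) / 2; cy <- (roi$y1 + roi$y2) / 2
    roi$x1 <- as.integer(floor(cx - side / 2)); roi$x2 <- roi$x1 + side
    roi$y1 <- as.integer(floor(cy - side / 2)); roi$y2 <- roi$y1 + side
    clamped <- TRUE
  }
  if (roi$x1 < 0)  { roi$x2 <- roi$x2 - roi$x1; roi$x1 <- 0L; clamped <- TRUE }
  if (roi$y1 < 0)  { roi$y2 <- roi$y2 - roi$y1; roi$y1 <- 0L; clamped <- TRUE }
  if (roi$x2 > nx) { roi$x1 <- roi$x1 - (roi$x2 - nx); roi$x2 <- as.integer(nx); clamped <- TRUE }
  if (roi$y2 > ny) { roi$y1 <- roi$y1 - (roi$y2 - ny); roi$y2 <- as.integer(ny); clamped <- TRUE }
  attr(roi, "clamped") <- clamped
  roi
}

#' Margins of a predicted mask inside its ROI
#'
#' Distances (in voxels) from each ROI edge to the nearest mask pixel, in
#' ROI-local coordinates: `d_left` is the smallest mask x index, `d_right`
#' the gap between the largest mask x index and the right edge, and likewise
#' `d_top` (low y) and `d_bottom` (high y).
#'
#' @param mask_2d binary matrix (rows = y, cols = x) in ROI-local
#'   coordinates.
#' @return a `mask_margins` list with `d_left, d_right, d_top, d_bottom`,
#'   the in-ROI `area`, and the mask's local bounding box; `NULL` when the
#'   mask is empty (the empty-mask signal that drives sweep stopping).
#' @export
compute_margins <- function(mask_2d) {
  idx <- which(mask_2d != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  ny <- nrow(mask_2d); nx <- ncol(mask_2d)
  xs <- idx[, 2] - 1L; ys <- idx[, 1] - 1L
  structure(list(
    d_left = min(xs), d_right = nx - 1L - max(xs),
    d_top = min(ys), d_bottom = ny - 1L - max(ys),
    area = nrow(idx),
    bbox = c(x_min = min(xs), x_max = max(xs),
             y_min = min(ys), y_max = max(ys))
  ), class = "mask_margins")
}

#' Recenter an ROI on its predicted mask
#'
#' Shifts the ROI so the mask margins become balanced:
#' `shift_x = round((d_left - d_right)/2)` (rounding half away from zero),
#' analogously in y. The side never changes; the result is translated back
#' inside the image if the shift would leave it.
#'
#' @param roi a [square_roi()].
#' @param margins a `mask_margins` from [compute_margins()].
#' @param image_extent `c(ny, nx)` of the slice.
#' @return a [square_roi()] for the same slice, with attribute `"clamped"`
#'   indicating whether image bounds forced a correction.
#' @export
recenter_roi <- function(roi, margins, image_extent) {
  stopifnot(inherits(roi, "square_roi"), inherits(margins, "mask_margins"))
  sx <- as.integer(round_half_away((margins$d_left - margins$d_right) / 2))
  sy <- as.integer(round_half_away((margins$d_top - margins$d_bottom) / 2))
  roi$x1 <- roi$x1 + sx; roi$x2 <- roi$x2 + sx
  roi$y1 <- roi$y1 + sy; roi$y2 <- roi$y2 + sy
  clamp_roi(roi, image_extent)
}

#' Adaptive-ROI configuration
#'
#' @param ratio_threshold upper bound `R_T` on the nodule-to-ROI area ratio,
#'   in `(0, 1)`. Smaller values give larger, looser ROIs; the reference
#'   operating point is 0.6.
#' @param resize_mode `"always"` (the side tracks `ceil(sqrt(A_N / R_T))` in
#'   both directions, so the ROI can also shrink as the nodule thins out) or
#'   `"grow_only"` (the side only increases, and only when the ratio is
#'   violated).
#' @param min_side smallest allowed ROI side in voxels; guards against tiny
#'   ROIs being upscaled to the network resolution.
#' @param max_steps cap on propagation steps per direction.
#' @param stop_on_empty number of consecutive empty predictions that ends a
#'   sweep (1 stops immediately after the nodule's last slice).
#' @return an `aroi_config` list.
#' @export
aroi_config <- function(ratio_threshold = 0.6,
                        resize_mode = c("always", "grow_only"),
                        min_side = 8L, max_steps = Inf, stop_on_empty = 1L) {
  assert_that(ratio_threshold > 0 && ratio_threshold < 1,
              "ratio_threshold must lie in (0, 1)")
  assert_that(min_side >= 1, "min_side must be >= 1")
  assert_that(stop_on_empty >= 1, "stop_on_empty must be >= 1")
  structure(list(ratio_threshold = ratio_threshold,
                 resize_mode = match.arg(resize_mode),
                 min_side = as.integer(min_side),
                 max_steps = max_steps,
                 stop_on_empty = as.integer(stop_on_empty)),
            class = "aroi_config")
}

#' Resize an ROI to keep the nodule-to-ROI area ratio below threshold
#'
#' The required ROI area is `A_req = A_N / R_T`; the new side is
#' `ceil(sqrt(A_req))`, floored at `min_side` and capped by the image. The
#' change is applied symmetrically about the ROI centre, with any odd voxel
#' biased to the high-index side. In `grow_only` mode the ROI is returned
#' unchanged whenever the current ratio already satisfies the bound.
#'
#' @param roi a [square_roi()].
#' @param nodule_area predicted nodule area `A_N` (voxels, > 0).
#' @param cfg an [aroi_config()].
#' @param image_extent `c(ny, nx)`.
#' @return a [square_roi()] with attributes `"clamped"` (image bounds
#'   interfered) and `"at_min_side"` (the `min_side` floor was active).
#' @export
resize_roi <- function(roi, nodule_area, cfg, image_extent) {
  stopifnot(inherits(roi, "square_roi"), inherits(cfg, "aroi_config"))
  if (is.null(nodule_area) || nodule_area <= 0) return(NULL)  # empty-mask signal
  side <- roi_side(roi)
  if (cfg$resize_mode == "grow_only" &&
      nodule_area / side^2 <= cfg$ratio_threshold) {
    attr(roi, "clamped") <- FALSE
    attr(roi, "at_min_side") <- FALSE
    return(roi)
  }
  new_side <- as.integer(ceiling(sqrt(nodule_area / cfg$ratio_threshold)))
  if (cfg$resize_mode == "grow_only") new_side <- max(new_side, side)
  at_min <- new_side < cfg$min_side
  new_side <- max(new_side, cfg$min_side)
  delta <- new_side - side
  lo <- delta %/% 2L                       # extra voxel goes to the high side
  hi <- delta - lo
  roi$x1 <- roi$x1 - lo; roi$x2 <- roi$x2 + hi
  roi$y1 <- roi$y1 - lo; roi$y2 <- roi$y2 + hi
  roi <- clamp_roi(roi, image_extent)
  attr(roi, "at_min_side") <- at_min
  roi
}
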
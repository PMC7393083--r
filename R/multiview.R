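# Stage II: coronal/sagittal patch-wise segmentation of the VOI.

#' Extract a coronal or sagittal slice stack from a VOI
#'
#' Coronal patches are one `(x, z)` slab per y position in the VOI;
#' sagittal patches one `(y, z)` slab per x position. The in-plane axis is
#' the patch's first (row) axis and z the second (column) axis, matching the
#' 128x64 network input where the coarser z axis maps to the narrow side.
#'
#' @param vol a [ct_volume()] (full grid).
#' @param voi a `voi_box` from [extract_voi()].
#' @param view `"coronal"` or `"sagittal"`.
#' @return a `view_stack`: list with `view`, `patches` (list of matrices),
#'   `index` (0-based absolute positions along the sweep axis), `voi`,
#'   `spacing`.
#' @export
extract_view_stack <- function(vol, voi, view = c("coronal", "sagittal")) {
  view <- match.arg(view)
  stopifnot(inherits(vol, "ct_volume"), inherits(voi, "voi_box"))
  d <- dim(vol$data)
  assert_that(voi$z2 <= d[1] && voi$y2 <= d[2] && voi$x2 <= d[3] &&
              min(voi$z1, voi$y1, voi$x1) >= 0,
              "VOI lies outside the volume")
  zz <- box_idx(voi$z1, voi$z2)
  if (view == "coronal") {
    sweep_idx <- seq.int(voi$y1, voi$y2 - 1L)
    xx <- box_idx(voi$x1, voi$x2)
    patches <- lapply(sweep_idx, function(y) {
      t(matrix(vol$data[zz, y + 1L, xx], length(zz), length(xx)))  # (x, z)
    })
  } else {
    sweep_idx <- seq.int(voi$x1, voi$x2 - 1L)
    yy <- box_idx(voi$y1, voi$y2)
    patches <- lapply(sweep_idx, function(x) {
      t(matrix(vol$data[zz, yy, x + 1L], length(zz), length(yy)))  # (y, z)
    })
  }
  structure(list(view = view, patches = patches, index = sweep_idx,
                 voi = voi, spacing = vol$spacing),
            class = "view_stack")
}

#' Segment a view stack patch-wise
#'
#' Each patch is handed to the segmenter (which resizes it to
#' `target_shape`, typically 128x64, and back), and the resulting binary
#' mask is inserted at its position in a VOI-shaped mask volume.
#'
#' @param stack a [extract_view_stack()] result.
#' @param segmenter a segmenter contract (see [as_segmenter()],
#'   [oracle_segmenter()]).
#' @param target_shape working resolution passed to the segmenter.
#' @return a [mask_volume()] with the VOI's shape.
#' @export
segment_view <- function(stack, segmenter, target_shape = c(128L, 64L)) {
  stopifnot(inherits(stack, "view_stack"))
  voi <- stack$voi
  nz <- voi$z2 - voi$z1; ny <- voi$y2 - voi$y1; nx <- voi$x2 - voi$x1
  out <- array(0L, c(nz, ny, nx))
  for (i in seq_along(stack$patches)) {
    patch <- stack$patches[[i]]
    info <- list(view = stack$view, index = stack$index[i], voi = voi)
    m <- segmenter(patch, target_shape, info)
    if (!is.matrix(m) || !identical(dim(m), dim(patch))) {
      stop("segmenter contract violation in ", stack$view, " view",
           call. = FALSE)
    }
    if (stack$view == "coronal") {
      out[, stack$index[i] - voi$y1 + 1L, ] <- t(m)      # (x,z) -> (z,x)
    } else {
      out[, , stack$index[i] - voi$x1 + 1L] <- t(m)      # (y,z) -> (z,y)
    }
  }
  mask_volume(out, stack$spacing)
}
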
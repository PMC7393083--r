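# Stage I: adaptive-ROI axial propagation.

# run a segmenter on one slice/ROI and validate its contract
run_segmenter <- function(segmenter, vol, roi, target_shape, info) {
  patch <- vol$data[roi$slice + 1L,
                    box_idx(roi$y1, roi$y2),
                    box_idx(roi$x1, roi$x2), drop = TRUE]
  patch <- matrix(patch, roi$y2 - roi$y1, roi$x2 - roi$x1)
  m <- segmenter(patch, target_shape, info)
  if (!is.matrix(m) || !identical(dim(m), dim(patch))) {
    stop("segmenter contract violation: output shape ",
         paste(dim(m), collapse = "x"), " != patch shape ",
         paste(dim(patch), collapse = "x"), call. = FALSE)
  }
  if (!all(m %in% c(0, 1))) {
    stop("segmenter contract violation: output is not binary", call. = FALSE)
  }
  m
}

#' Propagate a seed ROI across axial slices (adaptive-ROI algorithm)
#'
#' Stage I of the pipeline. The user-supplied seed ROI is segmented as given;
#' the prediction's margins then drive two independent sweeps (towards higher
#' and lower slice indices). At each step the ROI from the previous slice is
#' recentred on the previous prediction ([recenter_roi()]) and resized so the
#' predicted-nodule-to-ROI area ratio stays at or below
#' `cfg$ratio_threshold` ([resize_roi()]); the next slice's patch is then
#' extracted and segmented. A sweep ends at the volume boundary, after
#' `cfg$max_steps` steps, or after `cfg$stop_on_empty` consecutive empty
#' predictions — i.e. immediately after the end of the nodule for the
#' default of 1.
#'
#' The per-slice ROI trajectory is attached as attribute `"trace"`, a
#' data.frame with one row per segmented slice: ROI coordinates, the
#' intermediate recentred ROI, predicted area, the area ratio of the
#' previous prediction to the emitted ROI, and clamping flags. It backs both
#' the JSON propagation report and the geometric invariant checks.
#'
#' @param vol a [ct_volume()] (typically windowed to `[0, 1]`).
#' @param seed_roi a [square_roi()] supplied by the user; used exactly as
#'   given for the first segmentation.
#' @param segmenter a segmenter contract: `function(patch, target_shape,
#'   info)` returning a binary matrix shaped like `patch`. See
#'   [as_segmenter()] and [oracle_segmenter()].
#' @param cfg an [aroi_config()].
#' @param target_shape resolution the segmenter works at (passed through).
#' @return a [mask_volume()] on the full volume grid with attribute
#'   `"trace"`.
#' @export
propagate_axial <- function(vol, seed_roi, segmenter, cfg = aroi_config(),
                            target_shape = c(128L, 128L)) {
  stopifnot(inherits(vol, "ct_volume"), inherits(seed_roi, "square_roi"))
  d <- dim(vol$data)
  extent <- d[2:3]
  assert_that(seed_roi$x1 >= 0 && seed_roi$x2 <= d[3] &&
              seed_roi$y1 >= 0 && seed_roi$y2 <= d[2] &&
              seed_roi$slice >= 0 && seed_roi$slice < d[1],
              "seed ROI lies outside the volume")
  out <- array(0L, d)
  trace <- list()
  add_trace <- function(roi, rc_roi, area, prev_area, direction,
                        clamped_rc, clamped_rs, at_min) {
    trace[[length(trace) + 1L]] <<- data.frame(
      z = roi$slice, direction = direction,
      x1 = roi$x1, x2 = roi$x2, y1 = roi$y1, y2 = roi$y2,
      side = roi_side(roi),
      rc_x1 = rc_roi$x1, rc_x2 = rc_roi$x2,
      rc_y1 = rc_roi$y1, rc_y2 = rc_roi$y2,
      area = area, prev_area = prev_area,
      ratio_prev = prev_area / roi_side(roi)^2,
      clamped_recenter = clamped_rc, clamped_resize = clamped_rs,
      at_min_side = at_min, empty = area == 0L)
  }
  write_mask_at <- function(m, roi) {
    yy <- box_idx(roi$y1, roi$y2); xx <- box_idx(roi$x1, roi$x2)
    out[roi$slice + 1L, yy, xx] <<- pmax(out[roi$slice + 1L, yy, xx],
                                         matrix(as.integer(m), length(yy)))
  }

  seed_pred <- run_segmenter(segmenter, vol, seed_roi, target_shape,
                             list(view = "axial", slice = seed_roi$slice,
                                  roi = seed_roi))
  add_trace(seed_roi, seed_roi, sum(seed_pred), NA_integer_, 0L,
            FALSE, FALSE, FALSE)
  if (sum(seed_pred) == 0L) {
    warning("no nodule found in the seed ROI; returning an empty mask")
    res <- mask_volume(out, vol$spacing)
    attr(res, "trace") <- do.call(rbind, trace)
    return(res)
  }
  write_mask_at(seed_pred, seed_roi)

  for (direction in c(1L, -1L)) {
    roi <- seed_roi
    adjust_pred <- seed_pred      # last non-empty prediction, local to its ROI
    empty_run <- 0L
    steps <- 0L
    z <- seed_roi$slice
    repeat {
      z <- z + direction
      steps <- steps + 1L
      if (z < 0L || z >= d[1] || steps > cfg$max_steps) break
      clamped_rc <- FALSE; clamped_rs <- FALSE; at_min <- FALSE
      rc_roi <- roi
      if (!is.null(adjust_pred)) {
        mg <- compute_margins(adjust_pred)
        rc_roi <- recenter_roi(roi, mg, extent)
        clamped_rc <- isTRUE(attr(rc_roi, "clamped"))
        roi2 <- resize_roi(rc_roi, mg$area, cfg, extent)
        clamped_rs <- isTRUE(attr(roi2, "clamped"))
        at_min <- isTRUE(attr(roi2, "at_min_side"))
        roi <- roi2
      }
      prev_area <- if (is.null(adjust_pred)) NA_integer_ else sum(adjust_pred)
      roi$slice <- z
      rc_roi$slice <- z
      m <- run_segmenter(segmenter, vol, roi, target_shape,
                         list(view = "axial", slice = z, roi = roi))
      add_trace(roi, rc_roi, sum(m), prev_area, direction,
                clamped_rc, clamped_rs, at_min)
      if (sum(m) == 0L) {
        empty_run <- empty_run + 1L
        adjust_pred <- NULL       # nothing to recenter on; keep the ROI
        if (empty_run >= cfg$stop_on_empty) break
      } else {
        empty_run <- 0L
        adjust_pred <- m
        write_mask_at(m, roi)
      }
    }
  }
  res <- mask_volume(out, vol$spacing)
  tr <- do.call(rbind, trace)
  attr(res, "trace") <- tr[order(tr$z), ]
  res
}

#' Extract the volume of interest from a stage-I mask
#'
#' Tight bounding box of all foreground voxels, expanded by `pad` voxels on
#' all six sides and clipped to the volume.
#'
#' @param stage1_mask a [mask_volume()].
#' @param pad padding in voxels (default 2).
#' @return a `voi_box` with 0-based half-open fields
#'   `z1, z2, y1, y2, x1, x2`, or `NULL` when the mask is empty (the
#'   empty-result signal).
#' @export
extract_voi <- function(stage1_mask, pad = 2L) {
  stopifnot(inherits(stage1_mask, "mask_volume"))
  idx <- which(stage1_mask$data != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  d <- dim(stage1_mask$data)
  lo <- unname(pmax(apply(idx, 2, min) - 1L - pad, 0L))
  hi <- unname(pmin(apply(idx, 2, max) + pad, d))
  structure(list(z1 = lo[1], z2 = hi[1],
                 y1 = lo[2], y2 = hi[2],
                 x1 = lo[3], x2 = hi[3]),
            class = "voi_box")
}

#' @export
print.voi_box <- function(x, ...) {
  cat(sprintf("<voi_box> z [%d,%d), y [%d,%d), x [%d,%d)\n",
              x$z1, x$z2, x$y1, x$y2, x$x1, x$x2))
  invisible(x)
}

# crop helpers
crop_to_voi <- function(obj, voi) {
  zz <- box_idx(voi$z1, voi$z2); yy <- box_idx(voi$y1, voi$y2)
  xx <- box_idx(voi$x1, voi$x2)
  if (inherits(obj, "mask_volume")) {
    mask_volume(obj$data[zz, yy, xx, drop = FALSE], obj$spacing)
  } else {
    ct_volume(obj$data[zz, yy, xx, drop = FALSE], obj$spacing,
              origin = obj$origin,
              window_center = obj$window_center,
              window_width = obj$window_width)
  }
}
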
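# End-to-end orchestration of the two-stage pipeline.

#' Pipeline configuration
#'
#' Defaults follow the method's operating point: area-ratio threshold
#' `R_T = 0.6` for adaptive-ROI propagation and consensus ratio
#' `C_R = 0.5` for the three-view fusion.
#'
#' @param ratio_threshold `R_T` for stage I (see [aroi_config()]).
#' @param consensus_ratio `C_R` for the fusion (see [consensus_mask()]).
#' @param voi_pad padding (voxels) around the stage-I bounding box.
#' @param binarize_threshold threshold for model segmenters.
#' @param min_side,stop_on_empty,resize_mode passed to [aroi_config()].
#' @param axial_target,side_target working resolutions of the axial and
#'   coronal/sagittal segmenters.
#' @param preprocess normalise slice thickness and intensities before
#'   segmenting.
#' @param seed seed recorded in reports (the oracle path is deterministic).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(ratio_threshold = 0.6, consensus_ratio = 0.5,
                            voi_pad = 2L, binarize_threshold = 0.5,
                            min_side = 8L, stop_on_empty = 1L,
                            resize_mode = "always",
                            axial_target = c(128L, 128L),
                            side_target = c(128L, 64L),
                            preprocess = TRUE, seed = 1L) {
  structure(list(ratio_threshold = ratio_threshold,
                 consensus_ratio = consensus_ratio,
                 voi_pad = as.integer(voi_pad),
                 binarize_threshold = binarize_threshold,
                 min_side = as.integer(min_side),
                 stop_on_empty = as.integer(stop_on_empty),
                 resize_mode = resize_mode,
                 axial_target = as.integer(axial_target),
                 side_target = as.integer(side_target),
                 preprocess = isTRUE(preprocess),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

pick_segmenter <- function(segmenters, view) {
  if (is.function(segmenters)) return(segmenters)
  segmenters[[view]] %||% stop("no segmenter for view ", view, call. = FALSE)
}

#' Segment a nodule end to end
#'
#' Runs the full pipeline: optional preprocessing (slice-thickness
#' normalisation to the in-plane spacing, window-level intensity scaling),
#' stage I adaptive-ROI axial propagation, VOI extraction, stage II
#' coronal/sagittal patch-wise segmentation of the VOI, and voxel-majority
#' consensus of the three view masks. When a reference mask is supplied the
#' report carries per-stage DSC (axial, coronal, sagittal, consensus).
#'
#' @param vol a [ct_volume()].
#' @param seed_roi a [square_roi()] on the original grid (its slice index
#'   is remapped if preprocessing resamples z).
#' @param segmenters a single segmenter-contract function used for all
#'   views, or `list(axial =, coronal =, sagittal =)`. Note that when
#'   preprocessing is on, oracle segmenters must be built on the
#'   preprocessed grid (see `reference`).
#' @param config a [pipeline_config()].
#' @param reference optional ground-truth [mask_volume()] on the original
#'   grid (resampled along with the volume).
#' @return a `nodule_segmentation`: `mask` (final consensus on the
#'   processed grid), `status` (`"ok"` or `"no_nodule"`), `voi`,
#'   `stage_masks` (axial full-grid plus per-view VOI masks), `trace`
#'   (stage-I ROI trajectory), `report` (config echo, seeds, per-stage
#'   metrics when `reference` given), and `volume`/`reference` as
#'   processed.
#' @export
segment_nodule <- function(vol, seed_roi, segmenters,
                           config = pipeline_config(), reference = NULL) {
  stopifnot(inherits(vol, "ct_volume"), inherits(seed_roi, "square_roi"))
  if (config$preprocess) {
    sz_old <- vol$spacing[1]
    vol <- resample_z_to_pixel_spacing(vol)
    if (!is.null(vol$window_center) && max(vol$data) > 1) {
      vol <- normalize_intensity(vol)
    }
    if (!is.null(reference)) reference <- resample_z_mask(reference)
    new_slice <- as.integer(round(seed_roi$slice * sz_old / vol$spacing[1]))
    new_slice <- min(max(new_slice, 0L), dim(vol$data)[1] - 1L)
    seed_roi$slice <- new_slice
  }
  acfg <- aroi_config(ratio_threshold = config$ratio_threshold,
                      resize_mode = config$resize_mode,
                      min_side = config$min_side,
                      stop_on_empty = config$stop_on_empty)
  axial <- propagate_axial(vol, seed_roi, pick_segmenter(segmenters, "axial"),
                           acfg, target_shape = config$axial_target)
  trace <- attr(axial, "trace")
  report <- list(config = unclass(config), seed = config$seed,
                 n_slices_visited = nrow(trace))
  if (sum(axial$data) == 0L) {
    return(structure(list(mask = axial, status = "no_nodule", voi = NULL,
                          stage_masks = list(axial = axial), trace = trace,
                          report = report, volume = vol,
                          reference = reference),
                     class = "nodule_segmentation"))
  }
  voi <- extract_voi(axial, pad = config$voi_pad)
  axial_voi <- crop_to_voi(axial, voi)
  cor_mask <- segment_view(extract_view_stack(vol, voi, "coronal"),
                           pick_segmenter(segmenters, "coronal"),
                           target_shape = config$side_target)
  sag_mask <- segment_view(extract_view_stack(vol, voi, "sagittal"),
                           pick_segmenter(segmenters, "sagittal"),
                           target_shape = config$side_target)
  fused <- consensus_mask(list(axial_voi, cor_mask, sag_mask),
                          ratio = config$consensus_ratio)
  final <- array(0L, dim(vol$data))
  final[box_idx(voi$z1, voi$z2), box_idx(voi$y1, voi$y2),
        box_idx(voi$x1, voi$x2)] <- fused$data
  final <- mask_volume(final, vol$spacing)
  if (!is.null(reference)) {
    ref_voi <- crop_to_voi(reference, voi)
    report$metrics <- list(
      axial = evaluate_masks(axial, reference),
      coronal = evaluate_masks(cor_mask, ref_voi),
      sagittal = evaluate_masks(sag_mask, ref_voi),
      consensus = evaluate_masks(final, reference))
  }
  structure(list(mask = final, status = "ok", voi = voi,
                 stage_masks = list(axial = axial, axial_voi = axial_voi,
                                    coronal = cor_mask, sagittal = sag_mask),
                 trace = trace, report = report, volume = vol,
                 reference = reference),
            class = "nodule_segmentation")
}

#' @export
print.nodule_segmentation <- function(x, ...) {
  cat(sprintf("<nodule_segmentation> status: %s\n", x$status))
  if (!is.null(x$voi)) print(x$voi)
  cat(sprintf("  final mask: %d voxels (%.3g mm^3)\n",
              sum(x$mask$data), sum(x$mask$data) * prod(x$mask$spacing)))
  if (!is.null(x$report$metrics)) {
    for (nm in names(x$report$metrics)) {
      cat(sprintf("  %-9s DSC %.4f\n", nm, x$report$metrics[[nm]]$dsc))
    }
  }
  invisible(x)
}

#' Write the stage-I propagation report as JSON lines
#'
#' One record per segmented slice with the ROI coordinates, predicted
#' nodule area and area ratio.
#'
#' @param result a `nodule_segmentation`.
#' @param path output file.
#' @export
write_trace_jsonl <- function(result, path) {
  tr <- result$trace
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(tr))) {
    writeLines(jsonlite::toJSON(as.list(tr[i, ]), auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  }
  invisible(path)
}

#' Sensitivity sweep over the area-ratio threshold
#'
#' Re-runs the full pipeline over a suite of seeded phantoms for each value
#' of the ratio threshold `R_T`, with an oracle segmenter (optionally
#' noisy), and reports the mean and standard deviation of the consensus
#' DSC per `R_T`.
#'
#' @param rt_values numeric vector of thresholds in `(0, 1)`.
#' @param n_phantoms phantoms per grid point.
#' @param base_spec a [phantom_spec()] used as template; each phantom `i`
#'   uses seed `base_spec$seed + i`.
#' @param error_model,p oracle corruption (see [oracle_segmenter()]).
#' @param config a [pipeline_config()]; its `ratio_threshold` is replaced
#'   by each grid value in turn.
#' @return data.frame with columns `rt, mean_dsc, sd_dsc, n`.
#' @export
rt_sweep <- function(rt_values, n_phantoms = 10L,
                     base_spec = phantom_spec(),
                     error_model = "none", p = 0.3,
                     config = pipeline_config()) {
  assert_that(all(rt_values > 0 & rt_values < 1),
              "rt_values must lie in (0, 1)")
  phantoms <- lapply(seq_len(n_phantoms), function(i) {
    sp <- base_spec; sp$seed <- base_spec$seed + i
    generate_phantom(sp)
  })
  rows <- lapply(rt_values, function(rt) {
    cfg <- config; cfg$ratio_threshold <- rt
    dscs <- vapply(phantoms, function(ph) {
      run_phantom_pipeline(ph, cfg, error_model = error_model, p = p)$dsc
    }, numeric(1))
    data.frame(rt = rt, mean_dsc = mean(dscs), sd_dsc = stats::sd(dscs),
               n = n_phantoms)
  })
  do.call(rbind, rows)
}

# run one phantom through the pipeline with an oracle segmenter built on the
# preprocessed grid; returns per-stage DSC
run_phantom_pipeline <- function(ph, config = pipeline_config(),
                                 error_model = "none", p = 0.3,
                                 seed = 0L) {
  vol <- ph$volume; truth <- ph$mask
  if (config$preprocess) {
    vol <- normalize_intensity(resample_z_to_pixel_spacing(vol))
    truth <- resample_z_mask(truth)
  }
  cfg <- config; cfg$preprocess <- FALSE
  zs <- which(apply(truth$data, 1, sum) > 0) - 1L
  z0 <- zs[ceiling(length(zs) / 2)]
  bb <- compute_margins(truth$data[z0 + 1L, , ])$bbox
  sq <- square_up(bb["x_min"], bb["x_max"] + 1L, bb["y_min"], bb["y_max"] + 1L)
  seed_roi <- clamp_roi(square_roi(z0, sq[1], sq[3], sq[2] - sq[1]),
                        dim(vol$data)[2:3])
  seg <- oracle_segmenter(truth, error_model = error_model, p = p,
                          seed = seed)
  res <- segment_nodule(vol, seed_roi, seg, cfg, reference = truth)
  list(result = res,
       dsc = if (res$status == "ok") res$report$metrics$consensus$dsc else 0,
       metrics = res$report$metrics)
}
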
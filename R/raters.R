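# Multi-rater ground-truth construction (LIDC-style annotation handling).
#
# The public LIDC-IDRI archive provides four radiologists' contours per
# nodule; studies using it build the reference mask with a 50% consensus
# over the raters and keep nodules all four annotated with diameter >= 3 mm.
# These helpers implement that protocol on generic mask volumes so it can
# be applied to any locally rasterised annotation set (or synthetic raters
# in tests); the package ships no scan data.

#' Fuse rater annotations into a consensus ground truth
#'
#' Applies the same voxel-majority rule as the view fusion
#' ([consensus_mask()]) across `M` rater masks with a 50% consensus ratio
#' by default — a 2-of-4 rule for four raters.
#'
#' @param rater_masks list of aligned [mask_volume()]s, one per rater.
#' @param ratio consensus ratio (default 0.5).
#' @return a [mask_volume()].
#' @export
rater_consensus <- function(rater_masks, ratio = 0.5) {
  consensus_mask(rater_masks, ratio = ratio)
}

#' Maximum in-plane nodule diameter in millimetres
#'
#' The largest axial-slice bounding-box side, converted to mm — the
#' screening measure used to filter sub-3 mm lesions.
#'
#' @param mask a [mask_volume()].
#' @return diameter in mm (0 for an empty mask).
#' @export
nodule_diameter_mm <- function(mask) {
  stopifnot(inherits(mask, "mask_volume"))
  best <- 0
  for (z in seq_len(dim(mask$data)[1])) {
    mg <- compute_margins(mask$data[z, , ])
    if (is.null(mg)) next
    w_mm <- (mg$bbox["x_max"] - mg$bbox["x_min"] + 1) * mask$spacing[3]
    h_mm <- (mg$bbox["y_max"] - mg$bbox["y_min"] + 1) * mask$spacing[2]
    best <- max(best, w_mm, h_mm)
  }
  unname(best)
}

#' Build ground truth from rater annotations with inclusion filtering
#'
#' For each candidate nodule (a list of per-rater masks), requires
#' annotations from all `n_raters` raters and a consensus-mask diameter of
#' at least `min_diameter_mm`; returns the consensus masks of the nodules
#' that pass.
#'
#' @param nodules list of candidates; each a list of per-rater
#'   [mask_volume()]s.
#' @param n_raters required number of raters (default 4).
#' @param min_diameter_mm minimum diameter (default 3).
#' @param ratio consensus ratio (default 0.5).
#' @return list of consensus [mask_volume()]s (possibly empty).
#' @export
select_consensus_nodules <- function(nodules, n_raters = 4L,
                                     min_diameter_mm = 3,
                                     ratio = 0.5) {
  out <- list()
  for (cand in nodules) {
    if (length(cand) < n_raters) next
    if (any(vapply(cand, function(m) sum(m$data) == 0, logical(1)))) next
    cons <- rater_consensus(cand, ratio = ratio)
    if (nodule_diameter_mm(cons) < min_diameter_mm) next
    out[[length(out) + 1L]] <- cons
  }
  out
}
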
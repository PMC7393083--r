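#' Voxel-majority consensus of aligned masks
#'
#' Per voxel, the votes of the `M` input masks are summed; a voxel enters
#' the fused mask iff the vote count `g` satisfies `g >= M * ratio`. With
#' the default ratio of 0.5 this is a 50% consensus — a 2-of-3 rule for the
#' three view masks and a 2-of-4 rule for four raters' annotations (the
#' inclusive `>=` puts the exact-half case in the mask).
#'
#' @param masks list of [mask_volume()]s (or plain arrays) with identical
#'   shapes and spacings.
#' @param ratio consensus ratio `C_R` in `(0, 1]`.
#' @return a [mask_volume()].
#' @export
consensus_mask <- function(masks, ratio = 0.5) {
  assert_that(is.list(masks) && length(masks) >= 1L,
              "need at least one mask")
  assert_that(ratio > 0 && ratio <= 1, "ratio must lie in (0, 1]")
  m0 <- masks[[1]]
  spacing <- if (inherits(m0, "mask_volume")) m0$spacing else c(1, 1, 1)
  arr <- function(m) if (inherits(m, "mask_volume")) m$data else as.array(m)
  ref <- arr(m0)
  g <- array(0L, dim(ref))
  for (m in masks) {
    a <- arr(m)
    assert_that(identical(dim(a), dim(ref)), "mask shapes differ")
    if (inherits(m, "mask_volume")) {
      assert_that(isTRUE(all.equal(m$spacing, spacing, tolerance = 1e-6)),
                  "mask spacings differ")
    }
    g <- g + a
  }
  M <- length(masks)
  mask_volume((g >= M * ratio) * 1L, spacing)
}
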
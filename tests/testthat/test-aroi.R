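# independent replay of one recenter+resize step, written from the update
# rules directly (no package geometry functions)
replay_step <- function(roi, pred_local, rt, min_side) {
  idx <- which(pred_local != 0, arr.ind = TRUE)
  xs <- idx[, 2] - 1; ys <- idx[, 1] - 1
  side <- roi$x2 - roi$x1
  dl <- min(xs); dr <- side - 1 - max(xs)
  dt <- min(ys); db <- side - 1 - max(ys)
  half_away <- function(v) sign(v) * floor(abs(v) + 0.5)
  sx <- half_away((dl - dr) / 2); sy <- half_away((dt - db) / 2)
  x1 <- roi$x1 + sx; y1 <- roi$y1 + sy
  new_side <- max(ceiling(sqrt(nrow(idx) / rt)), min_side)
  delta <- new_side - side
  lo <- floor(delta / 2)
  list(x1 = x1 - lo, y1 = y1 - lo, side = new_side)
}

test_that("propagation with the exact oracle recovers convex phantoms slice by slice", {
  ph <- small_phantom(seed = 11)
  pp <- prep_phantom(ph)
  seed_roi <- middle_seed_roi(pp$truth)
  seg <- oracle_segmenter(pp$truth)
  out <- propagate_axial(pp$vol, seed_roi, seg, aroi_config())
  expect_gte(dsc(out, pp$truth), 0.99)
  tr <- attr(out, "trace")
  # per-slice DSC is 1 wherever the ROI fully covered the in-slice truth
  for (i in seq_len(nrow(tr))) {
    if (tr$empty[i]) next
    z <- tr$z[i]
    sl_truth <- pp$truth$data[z + 1, , ]
    sl_pred <- out$data[z + 1, , ]
    idx <- which(sl_truth != 0, arr.ind = TRUE) - 1L
    covered <- all(idx[, 2] >= tr$x1[i] & idx[, 2] < tr$x2[i] &
                   idx[, 1] >= tr$y1[i] & idx[, 1] < tr$y2[i])
    if (covered) expect_equal(sum(sl_pred != sl_truth), 0)
  }
})

test_that("the emitted ROI sequence matches an independent step-by-step replay", {
  ph <- small_phantom(seed = 12)
  pp <- prep_phantom(ph)
  seed_roi <- middle_seed_roi(pp$truth)
  cfg <- aroi_config(ratio_threshold = 0.6, min_side = 8)
  out <- propagate_axial(pp$vol, seed_roi, oracle_segmenter(pp$truth), cfg)
  tr <- attr(out, "trace")
  for (direction in c(1L, -1L)) {
    sub <- tr[tr$direction == direction & !tr$empty, ]
    sub <- sub[order(sub$z * direction), ]
    roi <- list(x1 = seed_roi$x1, x2 = seed_roi$x2,
                y1 = seed_roi$y1, y2 = seed_roi$y2)
    z <- seed_roi$slice
    pred <- pp$truth$data[z + 1, (roi$y1 + 1):roi$y2, (roi$x1 + 1):roi$x2]
    for (i in seq_len(nrow(sub))) {
      if (sub$clamped_recenter[i] || sub$clamped_resize[i]) break
      stp <- replay_step(roi, pred, 0.6, 8)
      expect_equal(sub$x1[i], stp$x1)
      expect_equal(sub$y1[i], stp$y1)
      expect_equal(sub$side[i], stp$side)
      roi <- list(x1 = stp$x1, x2 = stp$x1 + stp$side,
                  y1 = stp$y1, y2 = stp$y1 + stp$side)
      z <- sub$z[i]
      pred <- pp$truth$data[z + 1, (roi$y1 + 1):roi$y2, (roi$x1 + 1):roi$x2]
    }
  }
})

test_that("an empty seed prediction yields an empty mask and no sweeps", {
  ph <- small_phantom(seed = 13)
  pp <- prep_phantom(ph)
  far_roi <- square_roi(1, 0, 0, 10)   # corner far from the nodule
  expect_warning(
    out <- propagate_axial(pp$vol, far_roi, oracle_segmenter(pp$truth)),
    "no nodule")
  expect_equal(sum(out$data), 0)
  expect_equal(nrow(attr(out, "trace")), 1)
})

test_that("sweeps stop within stop_on_empty slices of the nodule's end", {
  ph <- small_phantom(seed = 14)
  pp <- prep_phantom(ph)
  zs <- which(apply(pp$truth$data, 1, sum) > 0) - 1L
  nz <- dim(pp$vol$data)[1]
  for (soe in c(1L, 2L)) {
    out <- propagate_axial(pp$vol, middle_seed_roi(pp$truth),
                           oracle_segmenter(pp$truth),
                           aroi_config(stop_on_empty = soe))
    tr <- attr(out, "trace")
    expect_lte(max(tr$z), min(max(zs) + soe, nz - 1))
    expect_gte(min(tr$z), max(min(zs) - soe, 0))
  }
})

test_that("identical inputs give identical ROI traces (determinism)", {
  ph <- small_phantom(seed = 15)
  pp <- prep_phantom(ph)
  roi <- middle_seed_roi(pp$truth)
  t1 <- attr(propagate_axial(pp$vol, roi, oracle_segmenter(pp$truth)), "trace")
  t2 <- attr(propagate_axial(pp$vol, roi, oracle_segmenter(pp$truth)), "trace")
  expect_identical(t1, t2)
})

test_that("a wrong-shaped segmenter output is a contract violation", {
  ph <- small_phantom(seed = 16)
  pp <- prep_phantom(ph)
  bad <- function(patch, target_shape, info) matrix(0, 2, 2)
  expect_error(propagate_axial(pp$vol, middle_seed_roi(pp$truth), bad),
               "contract violation")
})

test_that("VOI extraction pads and clips the foreground bounding box", {
  a <- array(0L, c(10, 10, 10)); a[6, 6, 6] <- 1L
  m <- mask_volume(a, c(1, 1, 1))
  voi <- extract_voi(m, pad = 2)
  expect_equal(unlist(voi[c("z1", "z2", "y1", "y2", "x1", "x2")]),
               c(z1 = 3, z2 = 8, y1 = 3, y2 = 8, x1 = 3, x2 = 8))

  full <- mask_volume(array(1L, c(4, 5, 6)), c(1, 1, 1))
  voi <- extract_voi(full, pad = 0)
  expect_equal(unlist(voi[c("z1", "z2", "y1", "y2", "x1", "x2")]),
               c(z1 = 0, z2 = 4, y1 = 0, y2 = 5, x1 = 0, x2 = 6))

  expect_null(extract_voi(mask_volume(array(0L, c(3, 3, 3)), c(1, 1, 1))))

  set.seed(17)
  for (i in 1:20) {
    a <- array((runif(5 * 8 * 8) > 0.9) * 1L, c(5, 8, 8))
    if (sum(a) == 0) next
    voi <- extract_voi(mask_volume(a, c(1, 1, 1)), pad = sample(0:3, 1))
    idx <- which(a == 1L, arr.ind = TRUE) - 1L
    expect_true(all(idx[, 1] >= voi$z1 & idx[, 1] < voi$z2 &
                    idx[, 2] >= voi$y1 & idx[, 2] < voi$y2 &
                    idx[, 3] >= voi$x1 & idx[, 3] < voi$x2))
  }
})
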
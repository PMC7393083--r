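test_that("phantom generation is deterministic per seed", {
  s <- phantom_spec(seed = 9)
  a <- generate_phantom(s); b <- generate_phantom(s)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mask$data, b$mask$data)
  s2 <- phantom_spec(seed = 10)
  expect_false(identical(generate_phantom(s2)$volume$data, a$volume$data))
})

test_that("the discretised ellipsoid volume approaches the analytic one on a fine grid", {
  sp <- phantom_spec(shape = c(48L, 64L, 64L), spacing = c(0.66, 0.66, 0.66),
                     semi_axes_mm = c(8, 10, 10), lobulation = 0,
                     noise_sd = 0, smooth_sigma = 0, seed = 2)
  ph <- generate_phantom(sp)
  analytic <- 4 / 3 * pi * prod(sp$semi_axes_mm)
  measured <- sum(ph$mask$data) * prod(sp$spacing)
  expect_lt(abs(measured - analytic) / analytic, 0.02)
})

test_that("a nodule that does not fit inside the grid is rejected", {
  expect_error(generate_phantom(phantom_spec(shape = c(6L, 20L, 20L),
                                             semi_axes_mm = c(20, 20, 20))),
               "does not fit")
})

test_that("the convex phantom mask is a single connected component", {
  ph <- small_phantom(seed = 20, lobulation = 0.3)
  m <- ph$mask$data
  # flood fill from one foreground voxel over 26-connectivity
  idx <- which(m == 1L, arr.ind = TRUE)
  visited <- array(FALSE, dim(m))
  queue <- list(idx[1, ])
  visited[idx[1, 1], idx[1, 2], idx[1, 3]] <- TRUE
  d <- dim(m)
  while (length(queue)) {
    v <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      w <- v + c(dz, dy, dx)
      if (any(w < 1) || any(w > d)) next
      if (m[w[1], w[2], w[3]] == 1L && !visited[w[1], w[2], w[3]]) {
        visited[w[1], w[2], w[3]] <- TRUE
        queue[[length(queue) + 1L]] <- w
      }
    }
  }
  expect_equal(sum(visited), sum(m))
})

test_that("the oracle segmenter returns exact truth crops and seeded corruptions", {
  ph <- small_phantom(seed = 21)
  truth <- ph$mask
  z0 <- middle_seed_roi(truth)$slice
  roi <- middle_seed_roi(truth)
  info <- list(view = "axial", slice = z0, roi = roi)
  patch <- matrix(0, roi$y2 - roi$y1, roi$x2 - roi$x1)
  exact <- oracle_segmenter(truth)(patch, NULL, info)
  expect_equal(exact,
               matrix(truth$data[z0 + 1, (roi$y1 + 1):roi$y2,
                                 (roi$x1 + 1):roi$x2] * 1.0,
                      roi$y2 - roi$y1))
  # flip_rate 0 is equivalent to no corruption
  flip0 <- oracle_segmenter(truth, "flip", flip_rate = 0, seed = 5)
  expect_equal(flip0(patch, NULL, info), exact)
  # erosion with p = 1 removes exactly the boundary ring of the crop
  er <- oracle_segmenter(truth, "erode", p = 1, seed = 5)(patch, NULL, info)
  ring <- exact - matrix(as.numeric(EBImage::erode(exact,
                                                   EBImage::makeBrush(3, "box"))),
                         nrow(exact))
  expect_equal(sum(exact) - sum(er), sum(ring))
  # deterministic per seed
  e1 <- oracle_segmenter(truth, "erode_dilate", p = 0.5, seed = 7)(patch, NULL, info)
  e2 <- oracle_segmenter(truth, "erode_dilate", p = 0.5, seed = 7)(patch, NULL, info)
  expect_identical(e1, e2)
})

test_that("training ROI margins are uniform on [0, D] and samples are labelled correctly", {
  ph <- small_phantom(seed = 22)
  pp <- prep_phantom(ph)
  samples <- sample_training_rois(pp$vol, pp$truth, n_per_slice = 2,
                                  include_non_nodule = 2, seed = 3)
  prov <- vapply(samples, function(s) s$provenance, character(1))
  expect_true(all(vapply(samples[prov == "nodule"],
                         function(s) sum(s$mask) >= 1, logical(1))))
  expect_true(all(vapply(samples[prov == "non_nodule"],
                         function(s) sum(s$mask) == 0, logical(1))))
  expect_true(all(vapply(samples, function(s)
    s$roi$x2 - s$roi$x1 == s$roi$y2 - s$roi$y1, logical(1))))

  # reproducibility of the margin sequence
  s2 <- sample_training_rois(pp$vol, pp$truth, n_per_slice = 2,
                             include_non_nodule = 2, seed = 3)
  expect_identical(lapply(samples, function(s) s$margins),
                   lapply(s2, function(s) s$margins))

  # chi-square uniformity of margins over many draws on one slice
  z0 <- middle_seed_roi(pp$truth)$slice
  one <- array(0L, dim(pp$truth$data))
  one[z0 + 1, , ] <- pp$truth$data[z0 + 1, , ]
  sl <- mask_volume(one, pp$truth$spacing)
  draws <- sample_training_rois(pp$vol, sl, n_per_slice = 2500, seed = 4)
  margins <- unlist(lapply(draws, function(s) s$margins))
  D <- max(margins)
  tab <- table(factor(margins, levels = 0:D))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.01)
})

test_that("zero margins give the tight square bounding box", {
  ph <- small_phantom(seed = 23)
  pp <- prep_phantom(ph)
  z0 <- middle_seed_roi(pp$truth)$slice
  bb <- compute_margins(pp$truth$data[z0 + 1, , ])$bbox
  long <- max(bb["x_max"] - bb["x_min"], bb["y_max"] - bb["y_min"]) + 1
  # the sampler's lower bound: a squared-up tight box has side = long side
  sq <- aroiseg:::square_up(bb["x_min"], bb["x_max"] + 1,
                            bb["y_min"], bb["y_max"] + 1)
  expect_equal(unname(sq[2] - sq[1]), unname(long))
  expect_equal(unname(sq[4] - sq[3]), unname(long))
})

test_that("blob patches pair each mask with an in-range intensity patch", {
  data <- make_blob_patches(20, c(24, 24), seed = 8)
  expect_equal(dim(data$patches), c(24, 24, 20))
  expect_true(all(data$patches >= 0 & data$patches <= 1))
  expect_true(all(data$masks %in% c(0, 1)))
  expect_true(all(apply(data$masks, 3, sum) > 0))
})
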
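# Parametric nodule phantoms with exact ground truth.
#
# These emulate the features of thoracic CT that matter for the geometry and
# fusion logic: anisotropic grids (slice thickness > in-plane spacing),
# blob-like nodules of varying size/lobulation spanning several slices,
# optional attached tubular (vessel-like) structures, and additive noise.
# They are not a physical CT simulator.

#' Phantom specification
#'
#' @param shape grid `(nz, ny, nx)` in voxels.
#' @param spacing `(sz, sy, sx)` in mm; the default mimics a thick-slice CT
#'   with 0.66 mm in-plane spacing and 2.5 mm slices.
#' @param center_mm nodule centre in mm `(z, y, x)`; default grid centre.
#' @param semi_axes_mm ellipsoid semi-axes `(az, ay, ax)` in mm.
#' @param lobulation radial perturbation amplitude in `[0, 1)`; 0 gives a
#'   pure ellipsoid, larger values lobulated (but still star-shaped) nodules.
#' @param background_hu,contrast_hu background intensity and nodule
#'   contrast (HU). Defaults: aerated-lung background -750 HU, nodule
#'   550 HU brighter.
#' @param smooth_sigma in-plane Gaussian smoothing sigma (voxels) applied
#'   to the intensity image (edge softness); 0 disables.
#' @param noise_sd additive Gaussian noise sigma (HU).
#' @param cylinder `NULL`, or `list(radius_mm =, axis =)` with axis
#'   `"x"`/`"y"` to attach a tube through the nodule centre (the
#'   juxta-vascular case). The tube is not part of the ground truth.
#' @param window `c(WC, WW)` stored on the volume (lung window default).
#' @param seed integer controlling all randomness in the phantom.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(24L, 96L, 96L),
                         spacing = c(2.5, 0.66, 0.66),
                         center_mm = NULL,
                         semi_axes_mm = c(8, 10, 10),
                         lobulation = 0.1,
                         background_hu = -750, contrast_hu = 550,
                         smooth_sigma = 0.8, noise_sd = 15,
                         cylinder = NULL,
                         window = c(-600, 1500),
                         seed = 1L) {
  assert_that(all(semi_axes_mm > 0), "semi-axes must be positive")
  assert_that(lobulation >= 0 && lobulation < 1,
              "lobulation must lie in [0, 1)")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 center_mm = center_mm, semi_axes_mm = semi_axes_mm,
                 lobulation = lobulation, background_hu = background_hu,
                 contrast_hu = contrast_hu, smooth_sigma = smooth_sigma,
                 noise_sd = noise_sd, cylinder = cylinder,
                 window = window, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a nodule phantom with exact ground truth
#'
#' The ground-truth mask is a (possibly radially perturbed) ellipsoid
#' evaluated at voxel centres; the intensity volume adds the nodule (and
#' optional attached tube) at `contrast_hu` over the background, smooths
#' in-plane and adds Gaussian noise. Fully deterministic per
#' `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` (a [ct_volume()], HU) and `mask`
#'   (a [mask_volume()]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape; sp <- spec$spacing
  ctr <- spec$center_mm %||% ((d - 1) / 2 * sp)
  ext_lo <- ctr - spec$semi_axes_mm * (1 + spec$lobulation)
  ext_hi <- ctr + spec$semi_axes_mm * (1 + spec$lobulation)
  assert_that(all(ext_lo >= 0) && all(ext_hi <= (d - 1) * sp),
              "nodule does not fit inside the grid")
  z <- (seq_len(d[1]) - 1) * sp[1] - ctr[1]
  y <- (seq_len(d[2]) - 1) * sp[2] - ctr[2]
  x <- (seq_len(d[3]) - 1) * sp[3] - ctr[3]
  uz <- array(rep(z / spec$semi_axes_mm[1], times = d[2] * d[3]), d)
  uy <- array(rep(rep(y / spec$semi_axes_mm[2], each = d[1]), times = d[3]), d)
  ux <- array(rep(x / spec$semi_axes_mm[3], each = d[1] * d[2]), d)
  rho <- sqrt(uz^2 + uy^2 + ux^2)
  with_seed(spec$seed, {
    if (spec$lobulation > 0) {
      theta <- acos(ifelse(rho > 0, uz / pmax(rho, 1e-12), 1))
      phi <- atan2(uy, ux)
      a <- stats::rnorm(3); b <- stats::runif(3, 0, 2 * pi)
      g <- a[1] * cos(phi + b[1]) * sin(theta) +
           a[2] * cos(2 * phi + b[2]) * sin(theta)^2 +
           a[3] * cos(2 * theta + b[3])
      g <- g / max(abs(g))
      mask <- (rho <= 1 + spec$lobulation * g) * 1L
    } else {
      mask <- (rho <= 1) * 1L
    }
    body <- mask
    if (!is.null(spec$cylinder)) {
      r <- spec$cylinder$radius_mm
      dz2 <- (uz * spec$semi_axes_mm[1])^2
      tube <- if (identical(spec$cylinder$axis, "y")) {
        (dz2 + (ux * spec$semi_axes_mm[3])^2 <= r^2) * 1L
      } else {
        (dz2 + (uy * spec$semi_axes_mm[2])^2 <= r^2) * 1L
      }
      body <- pmax(body, tube)
    }
    vol <- spec$background_hu + spec$contrast_hu * body
    if (spec$smooth_sigma > 0) {
      for (i in seq_len(d[1])) {
        vol[i, , ] <- as.matrix(EBImage::gblur(vol[i, , ],
                                               sigma = spec$smooth_sigma))
      }
    }
    if (spec$noise_sd > 0) {
      vol <- vol + array(stats::rnorm(prod(d), sd = spec$noise_sd), d)
    }
    list(volume = ct_volume(vol, sp, window_center = spec$window[1],
                            window_width = spec$window[2]),
         mask = mask_volume(array(mask, d), sp))
  })
}

view_code <- function(view) {
  match(view, c("axial", "coronal", "sagittal"))
}

#' Ground-truth oracle segmenter
#'
#' A segmenter-contract test double: given a patch location (from the
#' `info` argument of the contract), it returns the ground truth restricted
#' to that patch, optionally corrupted. It decouples the geometric pipeline
#' (A-ROI propagation, multi-view fusion) from learned models in tests.
#'
#' Error models: `"none"`; `"erode"`/`"dilate"`, which with probability `p`
#' apply a one-voxel 3x3 morphological erosion/dilation to the patch mask;
#' `"erode_dilate"`, which with probability `p` applies one of the two at
#' random; `"flip"`, which flips each pixel independently with probability
#' `flip_rate`. All corruption is deterministic given `seed` and the patch
#' location.
#'
#' @param truth a [mask_volume()] on the same grid as the volume being
#'   segmented.
#' @param error_model one of `"none"`, `"erode"`, `"dilate"`,
#'   `"erode_dilate"`, `"flip"`.
#' @param p per-patch corruption probability for the morphological models.
#' @param flip_rate per-pixel flip probability for `"flip"`.
#' @param seed base seed for the per-patch corruption draws.
#' @return `function(patch, target_shape, info)` returning a binary matrix
#'   shaped like `patch`.
#' @export
oracle_segmenter <- function(truth,
                             error_model = c("none", "erode", "dilate",
                                             "erode_dilate", "flip"),
                             p = 0.3, flip_rate = 0.05, seed = 0L) {
  stopifnot(inherits(truth, "mask_volume"))
  error_model <- match.arg(error_model)
  td <- dim(truth$data)
  function(patch, target_shape = NULL, info = NULL) {
    assert_that(!is.null(info), "oracle segmenter needs patch location info")
    if (identical(info$view, "axial")) {
      roi <- info$roi
      assert_that(roi$x1 >= 0 && roi$x2 <= td[3] &&
                  roi$y1 >= 0 && roi$y2 <= td[2] &&
                  info$slice >= 0 && info$slice < td[1],
                  "oracle patch lies outside the truth volume")
      m <- matrix(truth$data[info$slice + 1L,
                             box_idx(roi$y1, roi$y2),
                             box_idx(roi$x1, roi$x2)],
                  roi$y2 - roi$y1, roi$x2 - roi$x1)
      key <- info_hash(1L, info$slice, roi$x1, roi$y1, roi$x2)
    } else {
      voi <- info$voi
      zz <- box_idx(voi$z1, voi$z2)
      m <- if (identical(info$view, "coronal")) {
        t(matrix(truth$data[zz, info$index + 1L, box_idx(voi$x1, voi$x2)],
                 length(zz), voi$x2 - voi$x1))
      } else {
        t(matrix(truth$data[zz, box_idx(voi$y1, voi$y2), info$index + 1L],
                 length(zz), voi$y2 - voi$y1))
      }
      key <- info_hash(view_code(info$view), info$index,
                       voi$z1, voi$y1, voi$x1)
    }
    storage.mode(m) <- "double"
    if (error_model == "none") return(m)
    with_seed(seed * 7919 + key, {
      if (error_model == "flip") {
        flips <- matrix(stats::runif(length(m)) < flip_rate, nrow(m))
        m <- abs(m - flips)
      } else if (stats::runif(1) < p) {
        op <- switch(error_model,
                     erode = "erode", dilate = "dilate",
                     erode_dilate = sample(c("erode", "dilate"), 1))
        brush <- EBImage::makeBrush(3, "box")
        m <- if (op == "erode") {
          matrix(as.numeric(EBImage::erode(m, brush)), nrow(m))
        } else {
          matrix(as.numeric(EBImage::dilate(m, brush)), nrow(m))
        }
      }
      m
    })
  }
}

square_up <- function(x1, x2, y1, y2) {
  w <- x2 - x1; h <- y2 - y1
  if (w < h) {
    extra <- h - w; lo <- extra %/% 2L
    x1 <- x1 - lo; x2 <- x2 + (extra - lo)
  } else if (h < w) {
    extra <- w - h; lo <- extra %/% 2L
    y1 <- y1 - lo; y2 <- y2 + (extra - lo)
  }
  c(x1, x2, y1, y2)
}

#' Sample training ROIs with the random-margins strategy
#'
#' For each nodule-bearing axial slice, ROIs are drawn by padding the tight
#' in-slice bounding box with four independent margins, each uniform on
#' `[0, D]` where `D` is the in-slice maximum diameter (bounding-box long
#' side), then squaring the window up by expanding its short side. This
#' places the nodule at varying off-centre positions so a model learns to
#' find it anywhere in the ROI. Optionally, empty-mask ROIs are added from
#' slices just beyond both ends of the nodule so the model also learns
#' absence.
#'
#' @param vol a [ct_volume()].
#' @param truth the ground-truth [mask_volume()] (non-empty).
#' @param n_per_slice ROIs drawn per nodule-bearing slice.
#' @param include_non_nodule number of non-nodule slices to sample beyond
#'   each end of the nodule.
#' @param seed RNG seed; the sampled margin sequence is reproducible.
#' @return list of `roi_sample` lists: `patch`, `mask`, `roi`
#'   (a [square_roi()]), `margins` (the four draws), `provenance`
#'   (`"nodule"` or `"non_nodule"`).
#' @export
sample_training_rois <- function(vol, truth, n_per_slice = 1L,
                                 include_non_nodule = 0L, seed = 1L) {
  stopifnot(inherits(vol, "ct_volume"), inherits(truth, "mask_volume"))
  d <- dim(vol$data)
  extent <- d[2:3]
  zs <- which(apply(truth$data, 1, sum) > 0) - 1L
  assert_that(length(zs) > 0, "truth mask is empty")
  samples <- list()
  grab <- function(roi, z, provenance, margins) {
    patch <- matrix(vol$data[z + 1L, box_idx(roi$y1, roi$y2),
                             box_idx(roi$x1, roi$x2)],
                    roi$y2 - roi$y1, roi$x2 - roi$x1)
    msk <- matrix(truth$data[z + 1L, box_idx(roi$y1, roi$y2),
                             box_idx(roi$x1, roi$x2)],
                  roi$y2 - roi$y1, roi$x2 - roi$x1)
    structure(list(patch = patch, mask = msk, roi = roi,
                   margins = margins, provenance = provenance),
              class = "roi_sample")
  }
  with_seed(seed, {
    for (z in zs) {
      sl <- truth$data[z + 1L, , ]
      mg <- compute_margins(sl)
      bb <- mg$bbox
      D <- max(bb["x_max"] - bb["x_min"], bb["y_max"] - bb["y_min"]) + 1L
      for (rep_i in seq_len(n_per_slice)) {
        m4 <- sample.int(D + 1L, 4L, replace = TRUE) - 1L  # left,right,top,bottom
        x1 <- bb["x_min"] - m4[1]; x2 <- bb["x_max"] + 1L + m4[2]
        y1 <- bb["y_min"] - m4[3]; y2 <- bb["y_max"] + 1L + m4[4]
        sq <- square_up(x1, x2, y1, y2)
        roi <- square_roi(z, sq[1], sq[3], sq[2] - sq[1])
        roi <- clamp_roi(roi, extent)
        s <- grab(roi, z, "nodule", m4)
        if (sum(s$mask) == 0) {        # clamping pushed the nodule out: fall back
          sq <- square_up(bb["x_min"], bb["x_max"] + 1L,
                          bb["y_min"], bb["y_max"] + 1L)
          roi <- clamp_roi(square_roi(z, sq[1], sq[3], sq[2] - sq[1]), extent)
          s <- grab(roi, z, "nodule", c(0L, 0L, 0L, 0L))
        }
        samples[[length(samples) + 1L]] <- s
      }
    }
    if (include_non_nodule > 0) {
      for (end in c(min(zs), max(zs))) {
        ref_sl <- truth$data[end + 1L, , ]
        bb <- compute_margins(ref_sl)$bbox
        sq <- square_up(bb["x_min"], bb["x_max"] + 1L,
                        bb["y_min"], bb["y_max"] + 1L)
        dir <- if (end == min(zs)) -1L else 1L
        for (off in seq_len(include_non_nodule)) {
          z <- end + dir * off
          if (z < 0 || z >= d[1]) next
          roi <- clamp_roi(square_roi(z, sq[1], sq[3], sq[2] - sq[1]), extent)
          samples[[length(samples) + 1L]] <- grab(roi, z, "non_nodule",
                                                  c(0L, 0L, 0L, 0L))
        }
      }
    }
  })
  samples
}

#' Generate random blob patches for small-scale training
#'
#' Self-contained 2-D training data: each patch holds a random soft-edged
#' elliptical blob at a random off-centre position over a noisy background,
#' with its exact binary mask. Intensities lie in `[0, 1]`.
#'
#' @param n number of patches.
#' @param shape `c(H, W)` of each patch.
#' @param seed RNG seed.
#' @return list with arrays `patches` and `masks`, both `(H, W, n)`.
#' @export
make_blob_patches <- function(n, shape = c(32L, 32L), seed = 1L) {
  H <- shape[1]; W <- shape[2]
  patches <- array(0, c(H, W, n))
  masks <- array(0, c(H, W, n))
  with_seed(seed, {
    for (i in seq_len(n)) {
      cy <- stats::runif(1, 0.3 * H, 0.7 * H)
      cx <- stats::runif(1, 0.3 * W, 0.7 * W)
      ry <- stats::runif(1, 0.12, 0.3) * H
      rx <- stats::runif(1, 0.12, 0.3) * W
      ang <- stats::runif(1, 0, pi)
      yy <- matrix(seq_len(H) - cy, H, W)
      xx <- matrix(seq_len(W) - cx, H, W, byrow = TRUE)
      u <- (cos(ang) * xx + sin(ang) * yy) / rx
      v <- (-sin(ang) * xx + cos(ang) * yy) / ry
      m <- (u^2 + v^2 <= 1) * 1
      img <- 0.35 + 0.4 * m
      img <- as.matrix(EBImage::gblur(img, sigma = 0.8))
      img <- img + matrix(stats::rnorm(H * W, sd = 0.06), H)
      patches[, , i] <- pmin(pmax(img, 0), 1)
      masks[, , i] <- m
    }
  })
  list(patches = patches, masks = masks)
}
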
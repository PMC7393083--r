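#' Window-level intensity normalisation
#'
#' Maps CT intensities into `[0, 1]` using the display window: with
#' `Min = WC - WW/2` and `Max = WC + WW/2`, intensities are clipped to
#' `[Min, Max]` and then rescaled as `(I - Min) / (Max - Min)`. Clipping
#' keeps the output in the unit interval for intensities outside the window
#' (everything below the window saturates at 0, above at 1), which is the
#' standard radiological windowing behaviour.
#'
#' @param vol a [ct_volume()] with `window_center`/`window_width` set, or
#'   explicit overrides below.
#' @param window_center,window_width optional overrides (HU).
#' @return a [ct_volume()] with values in `[0, 1]`; the window tags are kept
#'   so downstream code can tell the volume has been normalised.
#' @export
normalize_intensity <- function(vol, window_center = NULL, window_width = NULL) {
  stopifnot(inherits(vol, "ct_volume"))
  wc <- window_center %||% vol$window_center
  ww <- window_width %||% vol$window_width
  assert_that(!is.null(wc) && !is.null(ww), "window center/width unavailable")
  assert_that(ww > 0, "window width must be > 0")
  lo <- wc - ww / 2
  hi <- wc + ww / 2
  x <- pmin(pmax(vol$data, lo), hi)
  vol$data <- (x - lo) / (hi - lo)
  vol
}

# linear (intensities) or nearest (masks) sampling weights along z
z_resample_map <- function(nz, sz, sz_new) {
  nz_new <- as.integer(round(nz * sz / sz_new))
  assert_that(nz_new >= 1L, "resampled volume would be empty")
  t <- (seq_len(nz_new) - 1) * sz_new / sz      # position in source slice units
  t <- pmin(pmax(t, 0), nz - 1)
  lo <- pmin(floor(t), nz - 2)
  lo[nz == 1] <- 0
  w <- t - lo
  list(nz_new = nz_new, lo = as.integer(lo) + 1L, w = w,
       nearest = as.integer(round(t)) + 1L)
}

#' Normalise slice thickness to the in-plane pixel spacing
#'
#' Resamples the volume along z so the slice spacing equals the in-plane
#' pixel spacing (which must be isotropic within `tol`); the in-plane grid is
#' left untouched. The new slice count is `round(nz * sz / sy)`. Intensities
#' are interpolated linearly along z; companion masks use nearest-neighbour
#' sampling so they stay binary (see [resample_z_mask()]).
#'
#' @param vol a [ct_volume()].
#' @param tol relative tolerance on in-plane isotropy (default 1e-3).
#' @return a [ct_volume()] with isotropic-in-z spacing `(sy, sy, sx)`.
#' @export
resample_z_to_pixel_spacing <- function(vol, tol = 1e-3) {
  stopifnot(inherits(vol, "ct_volume"))
  sp <- vol$spacing
  assert_that(abs(sp[2] - sp[3]) <= tol * sp[2],
              "in-plane spacing is anisotropic; cannot define a target z spacing")
  if (abs(sp[1] - sp[2]) <= tol * sp[2]) return(vol)
  d <- dim(vol$data)
  m <- z_resample_map(d[1], sp[1], sp[2])
  out <- array(0, c(m$nz_new, d[2], d[3]))
  for (i in seq_len(m$nz_new)) {
    lo <- m$lo[i]; w <- m$w[i]
    out[i, , ] <- if (w == 0 || lo >= d[1]) vol$data[lo, , ]
                  else (1 - w) * vol$data[lo, , ] + w * vol$data[lo + 1L, , ]
  }
  ct_volume(out, spacing = c(sp[2], sp[2], sp[3]), origin = vol$origin,
            window_center = vol$window_center, window_width = vol$window_width)
}

#' Resample a mask along z with the mask interpolation rule
#'
#' Nearest-neighbour along z, matching the grid produced by
#' [resample_z_to_pixel_spacing()] for the companion volume.
#'
#' @param mask a [mask_volume()].
#' @param tol relative tolerance on in-plane isotropy.
#' @return a [mask_volume()] on the resampled grid.
#' @export
resample_z_mask <- function(mask, tol = 1e-3) {
  stopifnot(inherits(mask, "mask_volume"))
  sp <- mask$spacing
  assert_that(abs(sp[2] - sp[3]) <= tol * sp[2],
              "in-plane spacing is anisotropic")
  if (abs(sp[1] - sp[2]) <= tol * sp[2]) return(mask)
  d <- dim(mask$data)
  m <- z_resample_map(d[1], sp[1], sp[2])
  out <- array(0L, c(m$nz_new, d[2], d[3]))
  for (i in seq_len(m$nz_new)) {
    out[i, , ] <- mask$data[min(m$nearest[i], d[1]), , ]
  }
  mask_volume(out, spacing = c(sp[2], sp[2], sp[3]))
}
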
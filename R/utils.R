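# Internal helpers shared across modules.

# 0-based half-open [lo, hi) -> R subscript vector
box_idx <- function(lo, hi) {
  stopifnot(hi > lo)
  seq.int(lo + 1L, hi)
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) {
  trunc(x + sign(x) * 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic small-integer hash for per-call RNG seeding
info_hash <- function(...) {
  v <- unlist(list(...), use.names = FALSE)
  v <- as.integer(v[!is.na(v)])
  h <- 17L
  for (x in v) {
    h <- (h * 31L + (x %% 65536L)) %% 214748329L
  }
  h
}

# run expr with a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

#' Resize a 2-D patch
#'
#' Thin wrapper around [EBImage::resize()] used wherever patches are mapped to
#' and from a network's input resolution. Intensities are interpolated
#' bilinearly; binary masks must use `method = "nearest"` so the result stays
#' binary.
#'
#' @param x numeric matrix.
#' @param shape integer length-2, target `(nrow, ncol)`.
#' @param method `"bilinear"` or `"nearest"`.
#' @return matrix with `dim(x) == shape`.
#' @keywords internal
resize2d <- function(x, shape, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  shape <- as.integer(shape)
  if (identical(dim(x), shape)) return(x)
  filt <- if (method == "nearest") "none" else "bilinear"
  y <- EBImage::resize(x, w = shape[1], h = shape[2], filter = filt)
  y <- matrix(as.numeric(y), shape[1], shape[2])
  y
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
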
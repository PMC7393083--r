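#' Residual U-Net specification
#'
#' Describes a deep residual U-Net: an encoder of pre-activation residual
#' units that halve the spatial grid with stride-2 convolutions, a bridge,
#' and a mirrored decoder where each unit is preceded by 2x nearest-neighbour
#' up-sampling and concatenation with the matching encoder feature map. Every
#' unit is two (batch-norm, ReLU, 3x3 convolution) blocks with an identity
#' mapping from input to output; where shapes change the identity is a
#' stride-matched 1x1 projection. A final 1x1 convolution plus sigmoid
#' produces the segmentation map.
#'
#' With `k = length(filters)` the network has `2k - 1` levels and
#' `2(2k - 1) + 1` main-path convolution layers.
#'
#' @param input_shape `c(H, W)`; both must be divisible by
#'   `2^(length(filters) - 1)`.
#' @param filters channel widths per encoder level, shallow to bridge,
#'   e.g. `c(64, 128, 256, 512, 1024)`.
#' @return a `resunet_spec`.
#' @export
resunet_spec <- function(input_shape, filters) {
  input_shape <- as.integer(input_shape)
  filters <- as.integer(filters)
  k <- length(filters)
  assert_that(k >= 2L, "need at least two filter levels")
  assert_that(all(input_shape %% 2L^(k - 1L) == 0L),
              "input shape must be divisible by 2^(encoder depth)")
  structure(list(input_shape = input_shape, filters = filters,
                 n_levels = 2L * k - 1L,
                 n_conv_layers = 2L * (2L * k - 1L) + 1L),
            class = "resunet_spec")
}

#' Specification of the axial segmentation network
#'
#' 9 levels, 19 convolution layers, 128x128x1 in and out, with channel
#' widths 64/128/256/512 and a 1024-channel bridge at 8x8.
#' @return a [resunet_spec()]
#' @export
axial_network_spec <- function() {
  resunet_spec(c(128L, 128L), c(64L, 128L, 256L, 512L, 1024L))
}

#' Specification of the coronal/sagittal segmentation network
#'
#' 7 levels, 15 convolution layers, 128x64x1 in and out (the 64-wide axis is
#' z, coarser before slice-thickness normalisation), with a 512-channel
#' bridge at 16x8.
#' @return a [resunet_spec()]
#' @export
side_network_spec <- function() {
  resunet_spec(c(128L, 64L), c(64L, 128L, 256L, 512L))
}

#' Reference layer table for a specification
#'
#' One row per main-path convolution layer with its level, kernel, filter
#' count, stride and output shape; the audit of a built network
#' ([resunet_audit()]) must reproduce this table exactly.
#'
#' @param spec a [resunet_spec()].
#' @return data.frame with columns `level, conv, kernel, filters, stride,
#'   out_h, out_w, out_c`.
#' @export
resunet_spec_table <- function(spec) {
  stopifnot(inherits(spec, "resunet_spec"))
  k <- length(spec$filters)
  H <- spec$input_shape[1]; W <- spec$input_shape[2]
  rows <- list(); ci <- 0L
  add <- function(level, kernel, f, s, h, w) {
    ci <<- ci + 1L
    rows[[ci]] <<- data.frame(level = level, conv = ci, kernel = kernel,
                              filters = f, stride = s,
                              out_h = h, out_w = w, out_c = f)
  }
  for (lvl in seq_len(k)) {             # encoder + bridge
    s1 <- if (lvl == 1L) 1L else 2L
    h <- H %/% as.integer(2^(lvl - 1)); w <- W %/% as.integer(2^(lvl - 1))
    add(lvl, "3x3", spec$filters[lvl], s1, h, w)
    add(lvl, "3x3", spec$filters[lvl], 1L, h, w)
  }
  for (j in seq_len(k - 1L)) {          # decoder
    idx <- k - j
    h <- H %/% as.integer(2^(idx - 1)); w <- W %/% as.integer(2^(idx - 1))
    add(k + j, "3x3", spec$filters[idx], 1L, h, w)
    add(k + j, "3x3", spec$filters[idx], 1L, h, w)
  }
  add(2L * k, "1x1", 1L, 1L, H, W)      # output projection
  tab <- do.call(rbind, rows)
  tab$level[nrow(tab)] <- NA_integer_   # the head sits outside the levels
  tab
}

new_unit <- function(cin, cout, stride, stem = FALSE) {
  u <- list(
    bn1 = if (stem) NULL else nn_bn(cin),
    conv1 = nn_conv(3L, 3L, cin, cout, stride),
    bn2 = nn_bn(cout),
    conv2 = nn_conv(3L, 3L, cout, cout, 1L),
    proj = if (stride != 1L || cin != cout) nn_conv(1L, 1L, cin, cout, stride)
           else NULL,
    stem = stem
  )
  u
}

#' Build a residual U-Net
#'
#' Instantiates all layers of a [resunet_spec()] with He-initialised
#' weights. Deterministic for a given `seed`.
#'
#' @param spec a [resunet_spec()].
#' @param seed integer seed for weight initialisation.
#' @return object of class `resunet`.
#' @export
build_resunet <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "resunet_spec"))
  f <- spec$filters
  k <- length(f)
  with_seed(seed, {
    units <- vector("list", k)
    units[[1]] <- new_unit(1L, f[1], 1L, stem = TRUE)
    for (i in 2:k) units[[i]] <- new_unit(f[i - 1L], f[i], 2L)
    dec <- vector("list", k - 1L)
    for (j in seq_len(k - 1L)) {
      idx <- k - j
      cin <- f[idx + 1L] + f[idx]       # upsampled below + encoder skip
      dec[[j]] <- new_unit(cin, f[idx], 1L)
    }
    head <- nn_conv(1L, 1L, f[1], 1L, 1L)
    structure(list(spec = spec, units = units, dec = dec, head = head),
              class = "resunet")
  })
}

#' @export
print.resunet <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<resunet> %d levels, %d conv layers, input %dx%dx1, bridge %dx%dx%d\n",
    s$n_levels, s$n_conv_layers, s$input_shape[1], s$input_shape[2],
    s$input_shape[1] %/% 2L^(length(s$filters) - 1L),
    s$input_shape[2] %/% 2L^(length(s$filters) - 1L),
    s$filters[length(s$filters)]))
  invisible(x)
}

unit_fwd <- function(u, x, train = FALSE, want_cache = FALSE) {
  cache <- list(x_dim = dim(x))
  if (u$stem) {
    h1 <- x
  } else {
    b1 <- bn_fwd(u$bn1, x, train, want_cache)
    u$bn1 <- b1$layer
    h1 <- relu_fwd(b1$y)
    if (want_cache) { cache$bn1 <- b1$cache; cache$bn1_out <- b1$y }
  }
  c1 <- conv_fwd(u$conv1, h1, want_cache)
  a1 <- if (want_cache) c1$y else c1
  b2 <- bn_fwd(u$bn2, a1, train, want_cache)
  u$bn2 <- b2$layer
  h2 <- relu_fwd(b2$y)
  c2 <- conv_fwd(u$conv2, h2, want_cache)
  a2 <- if (want_cache) c2$y else c2
  if (is.null(u$proj)) {
    y <- a2 + x
  } else {
    pr <- conv_fwd(u$proj, x, want_cache)
    y <- a2 + (if (want_cache) pr$y else pr)
    if (want_cache) cache$proj <- pr$cache
  }
  if (want_cache) {
    cache$conv1 <- c1$cache; cache$bn2 <- b2$cache; cache$bn2_out <- b2$y
    cache$conv2 <- c2$cache
  }
  list(y = y, unit = u, cache = cache)
}

unit_bwd <- function(u, cache, dy) {
  g <- list()
  cb2 <- conv_bwd(u$conv2, cache$conv2, dy)
  g$conv2 <- cb2[c("dW", "db")]
  dh2 <- relu_bwd(cache$bn2_out, cb2$dx)
  bb2 <- bn_bwd(u$bn2, cache$bn2, dh2)
  g$bn2 <- bb2[c("dgamma", "dbeta")]
  cb1 <- conv_bwd(u$conv1, cache$conv1, bb2$dx)
  g$conv1 <- cb1[c("dW", "db")]
  if (u$stem) {
    dx <- cb1$dx
  } else {
    dh1 <- relu_bwd(cache$bn1_out, cb1$dx)
    bb1 <- bn_bwd(u$bn1, cache$bn1, dh1)
    g$bn1 <- bb1[c("dgamma", "dbeta")]
    dx <- bb1$dx
  }
  if (is.null(u$proj)) {
    dx <- dx + dy
  } else {
    pb <- conv_bwd(u$proj, cache$proj, dy)
    g$proj <- pb[c("dW", "db")]
    dx <- dx + pb$dx
  }
  list(dx = dx, grads = g)
}

# Full forward pass. Returns the sigmoid output, the (possibly updated,
# batch-norm running stats) model, caches for backprop when want_cache, and
# an audit table of main-path conv layers when record.
resunet_fwd <- function(model, x, train = FALSE, want_cache = FALSE,
                        record = FALSE) {
  k <- length(model$spec$filters)
  audit <- if (record) list() else NULL
  note <- function(level, layer, y, kernel) {
    if (record) {
      d <- dim(y)
      audit[[length(audit) + 1L]] <<- data.frame(
        level = level, kernel = kernel, filters = d[3],
        stride = layer$stride, out_h = d[1], out_w = d[2], out_c = d[3])
    }
  }
  skips <- vector("list", k)
  caches <- list(units = vector("list", k), dec = vector("list", k - 1L))
  cur <- x
  for (i in seq_len(k)) {
    r <- unit_fwd(model$units[[i]], cur, train, want_cache)
    model$units[[i]] <- r$unit
    caches$units[[i]] <- r$cache
    cur <- r$y
    skips[[i]] <- cur
    if (record) {
      note(i, model$units[[i]]$conv1, cur, "3x3")
      note(i, model$units[[i]]$conv2, cur, "3x3")
    }
  }
  for (j in seq_len(k - 1L)) {
    up <- upsample2_fwd(cur)
    cat_in <- concat_c(up, skips[[k - j]])
    if (want_cache) caches$dec_split[[j]] <- c(dim(up)[3], dim(skips[[k - j]])[3])
    r <- unit_fwd(model$dec[[j]], cat_in, train, want_cache)
    model$dec[[j]] <- r$unit
    caches$dec[[j]] <- r$cache
    cur <- r$y
    if (record) {
      note(k + j, model$dec[[j]]$conv1, cur, "3x3")
      note(k + j, model$dec[[j]]$conv2, cur, "3x3")
    }
  }
  hc <- conv_fwd(model$head, cur, want_cache)
  logits <- if (want_cache) hc$y else hc
  if (want_cache) caches$head <- hc$cache
  p <- sigmoid(logits)
  if (record) {
    note(NA_integer_, model$head, p, "1x1")
    audit <- do.call(rbind, audit)
    audit$conv <- seq_len(nrow(audit))
    audit <- audit[, c("level", "conv", "kernel", "filters", "stride",
                       "out_h", "out_w", "out_c")]
  }
  list(p = p, model = model, caches = caches, audit = audit)
}

# Backward pass from dL/dp. Returns gradients mirroring the model structure.
resunet_bwd <- function(model, caches, p, dp) {
  k <- length(model$spec$filters)
  dlogits <- dp * p * (1 - p)
  hb <- conv_bwd(model$head, caches$head, dlogits)
  grads <- list(units = vector("list", k), dec = vector("list", k - 1L),
                head = hb[c("dW", "db")])
  dcur <- hb$dx
  dskips <- vector("list", k)
  for (j in rev(seq_len(k - 1L))) {
    ub <- unit_bwd(model$dec[[j]], caches$dec[[j]], dcur)
    grads$dec[[j]] <- ub$grads
    cup <- caches$dec_split[[j]][1]
    dup <- ub$dx[, , seq_len(cup), , drop = FALSE]
    dskip <- ub$dx[, , cup + seq_len(dim(ub$dx)[3] - cup), , drop = FALSE]
    dskips[[k - j]] <- dskip
    dcur <- upsample2_bwd(dup)
  }
  for (i in rev(seq_len(k))) {
    if (!is.null(dskips[[i]])) dcur <- dcur + dskips[[i]]
    ub <- unit_bwd(model$units[[i]], caches$units[[i]], dcur)
    grads$units[[i]] <- ub$grads
    dcur <- ub$dx
  }
  grads
}

#' Audit a built network against its specification
#'
#' Runs a real forward pass on a zero-filled conforming input while
#' recording, for every main-path convolution layer, its level, kernel,
#' stride and actual output shape. Identity-projection convolutions are part
#' of the residual shortcuts and are not main-path layers.
#'
#' @param model a [build_resunet()] network.
#' @return data.frame with the same columns as [resunet_spec_table()].
#' @export
resunet_audit <- function(model) {
  stopifnot(inherits(model, "resunet"))
  x <- array(0, c(model$spec$input_shape, 1L, 1L))
  resunet_fwd(model, x, record = TRUE)$audit
}

#' Forward a batch of patches through the network
#'
#' @param object a `resunet`.
#' @param patches numeric array `(H, W, N)` or a single `(H, W)` matrix
#'   matching the spec's input shape.
#' @param ... unused.
#' @return array `(H, W, N)` of sigmoid probabilities in `(0, 1)`.
#' @export
predict.resunet <- function(object, patches, ...) {
  if (is.matrix(patches)) patches <- array(patches, c(dim(patches), 1L))
  d <- dim(patches)
  assert_that(all(d[1:2] == object$spec$input_shape),
              "patch shape does not match the network input shape")
  x <- array(patches, c(d[1], d[2], 1L, d[3]))
  p <- resunet_fwd(object, x)$p
  array(p, c(d[1], d[2], d[3]))
}
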
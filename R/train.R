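#' Soft dice loss
#'
#' Mean over the batch of `1 - 2 * sum(p * t) / (sum(p) + sum(t) + eps)`,
#' the overlap loss minimised during training. On binary predictions it
#' equals `1 - DSC` up to `eps`, which only guards the empty-empty 0/0 case.
#'
#' @param pred soft predictions in `[0, 1]`, array `(H, W, N)` or
#'   `(H, W, 1, N)` (or a single matrix).
#' @param truth binary masks, same shape.
#' @param eps denominator stabiliser (default 1e-7).
#' @return scalar loss in `[0, 1]` (up to `eps`).
#' @export
dice_loss <- function(pred, truth, eps = 1e-7) {
  assert_that(identical(dim(pred) %||% length(pred),
                        dim(truth) %||% length(truth)),
              "pred and truth shapes differ")
  assert_that(all(truth %in% c(0, 1)), "truth must be binary")
  pm <- sample_matrix(pred); tm <- sample_matrix(truth)
  num <- 2 * colSums(pm * tm)
  den <- colSums(pm) + colSums(tm) + eps
  mean(1 - num / den)
}

# flatten (H,W,[1,]N) to (voxels x N)
sample_matrix <- function(x) {
  if (is.null(dim(x))) return(matrix(x, ncol = 1))
  d <- dim(x)
  n <- d[length(d)]
  if (length(d) == 2L) matrix(x, ncol = 1) else matrix(x, ncol = n)
}

# dL/dpred of dice_loss, same shape as pred
dice_loss_grad <- function(pred, truth, eps = 1e-7) {
  d <- dim(pred)
  pm <- sample_matrix(pred); tm <- sample_matrix(truth)
  n <- ncol(pm)
  num <- 2 * colSums(pm * tm)
  den <- colSums(pm) + colSums(tm) + eps
  g <- sweep(-2 * tm, 2, den, "/") + sweep(matrix(1, nrow(pm), n), 2,
                                           num / den^2, "*")
  array(g / n, d)
}

#' Training configuration
#'
#' Defaults follow the reference training protocol: plain stochastic
#' gradient descent, learning rate 1e-4, mini-batches of 8, up to 700
#' epochs. `momentum` extends plain SGD (0 disables it); small scaled-down
#' networks train well with a larger learning rate plus momentum.
#'
#' @param learning_rate positive step size.
#' @param batch_size mini-batch size (>= 1).
#' @param epochs number of passes over the data.
#' @param momentum SGD momentum in `[0, 1)`.
#' @param seed integer; fixes shuffling (and hence the whole run).
#' @param binarize_threshold inference threshold on the sigmoid output.
#' @param verbose print per-epoch progress.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 8L,
                         epochs = 700L, momentum = 0, seed = 1L,
                         binarize_threshold = 0.5, verbose = FALSE) {
  assert_that(learning_rate > 0, "learning_rate must be > 0")
  assert_that(batch_size >= 1, "batch_size must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), momentum = momentum,
                 seed = as.integer(seed),
                 binarize_threshold = binarize_threshold,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

sgd_layer <- function(layer, g, st, lr, mom) {
  if (is.null(layer) || is.null(g)) return(list(layer = layer, st = st))
  fields <- if (layer$kind == "conv") c(W = "dW", b = "db")
            else c(gamma = "dgamma", beta = "dbeta")
  for (i in seq_along(fields)) {
    p <- names(fields)[i]; gp <- fields[[i]]
    v <- st[[p]] %||% (g[[gp]] * 0)
    v <- mom * v - lr * g[[gp]]
    layer[[p]] <- layer[[p]] + v
    st[[p]] <- v
  }
  list(layer = layer, st = st)
}

sgd_unit <- function(u, g, st, lr, mom) {
  st <- st %||% list()
  for (nm in c("bn1", "conv1", "bn2", "conv2", "proj")) {
    r <- sgd_layer(u[[nm]], g[[nm]], st[[nm]], lr, mom)
    u[[nm]] <- r$layer; st[[nm]] <- r$st
  }
  list(unit = u, st = st)
}

#' Train a residual U-Net with the dice loss under SGD
#'
#' Mini-batch SGD on [dice_loss()]. Runs are reproducible: all shuffling
#' derives from `cfg$seed`. Training aborts with diagnostics if the loss
#' turns non-finite.
#'
#' @param model a [build_resunet()] network.
#' @param patches array `(H, W, N)` of input patches (intensities in
#'   `[0, 1]`), matching the spec input shape.
#' @param masks array `(H, W, N)` of binary target masks.
#' @param cfg a [train_config()].
#' @param val_patches,val_masks optional held-out set; per-epoch validation
#'   DSC (thresholded at `cfg$binarize_threshold`) is recorded in the
#'   history.
#' @return list with elements `model` (trained) and `history` (data.frame
#'   of per-epoch train loss / train DSC / validation DSC).
#' @export
train_resunet <- function(model, patches, masks, cfg = train_config(),
                          val_patches = NULL, val_masks = NULL) {
  stopifnot(inherits(model, "resunet"), inherits(cfg, "train_config"))
  d <- dim(patches)
  assert_that(length(d) == 3L && all(d[1:2] == model$spec$input_shape),
              "patches must be (H, W, N) matching the network input shape")
  assert_that(identical(dim(masks), d), "masks must match patches")
  n <- d[3]
  state <- list(units = vector("list", length(model$units)),
                dec = vector("list", length(model$dec)), head = NULL)
  history <- vector("list", cfg$epochs)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      losses <- c(); dscs <- c()
      for (start in seq.int(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        xb <- array(patches[, , idx], c(d[1], d[2], 1L, length(idx)))
        yb <- array(masks[, , idx], c(d[1], d[2], 1L, length(idx)))
        fw <- resunet_fwd(model, xb, train = TRUE, want_cache = TRUE)
        model <- fw$model
        loss <- dice_loss(fw$p, yb)
        if (!is.finite(loss)) {
          stop(sprintf("non-finite loss at epoch %d (|p| range %.3g..%.3g)",
                       epoch, min(fw$p), max(fw$p)), call. = FALSE)
        }
        losses <- c(losses, loss)
        dscs <- c(dscs, 1 - dice_loss((fw$p >= cfg$binarize_threshold) * 1,
                                      yb))
        grads <- resunet_bwd(model, fw$caches, fw$p,
                             dice_loss_grad(fw$p, yb))
        for (i in seq_along(model$units)) {
          r <- sgd_unit(model$units[[i]], grads$units[[i]],
                        state$units[[i]], cfg$learning_rate, cfg$momentum)
          model$units[[i]] <- r$unit; state$units[[i]] <- r$st
        }
        for (j in seq_along(model$dec)) {
          r <- sgd_unit(model$dec[[j]], grads$dec[[j]],
                        state$dec[[j]], cfg$learning_rate, cfg$momentum)
          model$dec[[j]] <- r$unit; state$dec[[j]] <- r$st
        }
        r <- sgd_layer(model$head, grads$head, state$head,
                       cfg$learning_rate, cfg$momentum)
        model$head <- r$layer; state$head <- r$st
      }
      val_dsc <- NA_real_
      if (!is.null(val_patches)) {
        pv <- predict(model, val_patches)
        val_dsc <- 1 - dice_loss((pv >= cfg$binarize_threshold) * 1,
                                 val_masks)
      }
      history[[epoch]] <- data.frame(epoch = epoch,
                                     train_loss = mean(losses),
                                     train_dsc = mean(dscs),
                                     val_dsc = val_dsc)
      if (cfg$verbose) {
        message(sprintf("epoch %3d  loss %.4f  train DSC %.4f  val DSC %s",
                        epoch, mean(losses), mean(dscs),
                        ifelse(is.na(val_dsc), "-", sprintf("%.4f", val_dsc))))
      }
    }
  })
  list(model = model, history = do.call(rbind, history))
}

#' Wrap a trained network as a segmenter contract
#'
#' The returned function maps a 2-D patch to a binary mask of the same
#' shape: the patch is resized (bilinear) to the network's input
#' resolution, forwarded, thresholded, and the mask resized back with
#' nearest-neighbour interpolation so it stays binary.
#'
#' @param model a trained `resunet`.
#' @param threshold binarisation threshold on the sigmoid output.
#' @return `function(patch, target_shape, info)`; `target_shape` and `info`
#'   are part of the shared segmenter interface — the network's own input
#'   shape defines the working resolution.
#' @export
as_segmenter <- function(model, threshold = 0.5) {
  stopifnot(inherits(model, "resunet"))
  shp <- model$spec$input_shape
  function(patch, target_shape = NULL, info = NULL) {
    orig <- dim(patch)
    x <- resize2d(patch, shp, "bilinear")
    p <- predict(model, x)[, , 1]
    m <- (p >= threshold) * 1
    resize2d(m, orig, "nearest")
  }
}
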
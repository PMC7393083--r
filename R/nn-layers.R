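# Minimal convolutional network engine.
#
# Tensors are dense double arrays laid out (H, W, C, N). Convolutions use
# 'same' padding and are evaluated as a sum over kernel offsets of
# (pixels x Cin) %*% (Cin x Cout) matrix products, which hands all the heavy
# lifting to BLAS. Each layer has an explicit forward and backward; there is
# no autograd. This is deliberately small: the networks used here are fully
# specified up front and the training problems are patch-sized.

nn_conv <- function(kh, kw, cin, cout, stride = 1L) {
  # He-normal initialisation, suited to ReLU stacks
  w <- array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
             c(kh, kw, cin, cout))
  list(kind = "conv", W = w, b = numeric(cout), stride = as.integer(stride))
}

nn_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  list(kind = "bn", gamma = rep(1, c), beta = numeric(c),
       running_mean = numeric(c), running_var = rep(1, c),
       momentum = momentum, eps = eps)
}

conv_out_len <- function(n, s) as.integer(ceiling(n / s))

conv_fwd <- function(layer, x, want_cache = FALSE) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  kd <- dim(layer$W); kh <- kd[1]; kw <- kd[2]; cout <- kd[4]
  s <- layer$stride
  Ho <- conv_out_len(H, s); Wo <- conv_out_len(W, s)
  ph <- max((Ho - 1L) * s + kh - H, 0L); pw <- max((Wo - 1L) * s + kw - W, 0L)
  ph0 <- ph %/% 2L; pw0 <- pw %/% 2L
  if (ph > 0L || pw > 0L) {
    xp <- array(0, c(H + ph, W + pw, C, N))
    xp[ph0 + seq_len(H), pw0 + seq_len(W), , ] <- x
  } else xp <- x
  rows <- Ho * Wo * N
  acc <- matrix(0, rows, cout)
  for (di in seq_len(kh)) for (dj in seq_len(kw)) {
    ri <- seq.int(di, by = s, length.out = Ho)
    rj <- seq.int(dj, by = s, length.out = Wo)
    sub <- xp[ri, rj, , , drop = FALSE]
    mat <- matrix(aperm(sub, c(1, 2, 4, 3)), rows, C)
    acc <- acc + mat %*% matrix(layer$W[di, dj, , ], C, cout)
  }
  acc <- sweep(acc, 2, layer$b, "+")
  y <- aperm(array(acc, c(Ho, Wo, N, cout)), c(1, 2, 4, 3))
  if (!want_cache) return(y)
  list(y = y, cache = list(xp = xp, in_dim = d, ph0 = ph0, pw0 = pw0,
                           Ho = Ho, Wo = Wo))
}

conv_bwd <- function(layer, cache, dy) {
  d <- cache$in_dim; H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  kd <- dim(layer$W); kh <- kd[1]; kw <- kd[2]; cout <- kd[4]
  s <- layer$stride; Ho <- cache$Ho; Wo <- cache$Wo
  rows <- Ho * Wo * N
  dmat <- matrix(aperm(dy, c(1, 2, 4, 3)), rows, cout)
  db <- colSums(dmat)
  dW <- array(0, kd)
  dxp <- array(0, dim(cache$xp))
  for (di in seq_len(kh)) for (dj in seq_len(kw)) {
    ri <- seq.int(di, by = s, length.out = Ho)
    rj <- seq.int(dj, by = s, length.out = Wo)
    sub <- cache$xp[ri, rj, , , drop = FALSE]
    mat <- matrix(aperm(sub, c(1, 2, 4, 3)), rows, C)
    dW[di, dj, , ] <- crossprod(mat, dmat)
    dsub <- aperm(array(dmat %*% t(matrix(layer$W[di, dj, , ], C, cout)),
                        c(Ho, Wo, N, C)), c(1, 2, 4, 3))
    dxp[ri, rj, , ] <- dxp[ri, rj, , , drop = FALSE] + dsub
  }
  dx <- dxp[cache$ph0 + seq_len(H), cache$pw0 + seq_len(W), , , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

bn_fwd <- function(layer, x, train = FALSE, want_cache = FALSE) {
  d <- dim(x); C <- d[3]
  m <- d[1] * d[2] * d[4]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), m, C)
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean +
      layer$momentum * mu
    layer$running_var <- (1 - layer$momentum) * layer$running_var +
      layer$momentum * v
  } else {
    mu <- layer$running_mean
    v <- layer$running_var
  }
  invstd <- 1 / sqrt(v + layer$eps)
  xhat <- (xm - rep(mu, each = m)) * rep(invstd, each = m)
  ym <- xhat * rep(layer$gamma, each = m) + rep(layer$beta, each = m)
  y <- aperm(array(ym, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  if (!want_cache) return(list(y = y, layer = layer))
  list(y = y, layer = layer,
       cache = list(xhat = xhat, invstd = invstd, dims = d))
}

bn_bwd <- function(layer, cache, dy) {
  d <- cache$dims; C <- d[3]; m <- d[1] * d[2] * d[4]
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), m, C)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- dym * rep(layer$gamma, each = m)
  t1 <- colMeans(dxhat)
  t2 <- colMeans(dxhat * cache$xhat)
  dxm <- (dxhat - rep(t1, each = m) - cache$xhat * rep(t2, each = m)) *
    rep(cache$invstd, each = m)
  dx <- aperm(array(dxm, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(x, dy) dy * (x > 0)

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  a <- dy[seq.int(1, d[1], 2), , , , drop = FALSE] +
       dy[seq.int(2, d[1], 2), , , , drop = FALSE]
  a[, seq.int(1, d[2], 2), , , drop = FALSE] +
    a[, seq.int(2, d[2], 2), , , drop = FALSE]
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))
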
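test_that("a residual unit with zeroed convolutions is the identity path", {
  u <- aroiseg:::new_unit(3L, 3L, 1L)          # same channels, stride 1: no proj
  expect_null(u$proj)
  u$conv1$W[] <- 0; u$conv2$W[] <- 0
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  y <- aroiseg:::unit_fwd(u, x)$y
  expect_equal(y, x)
})

test_that("a stride-2 unit halves the spatial grid", {
  u <- aroiseg:::new_unit(4L, 8L, 2L)
  x <- array(rnorm(16 * 16 * 4 * 1), c(16, 16, 4, 1))
  y <- aroiseg:::unit_fwd(u, x)$y
  expect_equal(dim(y), c(8, 8, 8, 1))
})

test_that("analytic gradients match numerical differentiation", {
  spec <- resunet_spec(c(8, 8), c(3, 4))
  m <- build_resunet(spec, seed = 2)
  set.seed(9)
  x <- array(runif(8 * 8 * 2), c(8, 8, 1, 2))
  y <- array((runif(8 * 8 * 2) > 0.6) * 1, c(8, 8, 1, 2))
  fw <- aroiseg:::resunet_fwd(m, x, train = TRUE, want_cache = TRUE)
  g <- aroiseg:::resunet_bwd(fw$model, fw$caches, fw$p,
                             aroiseg:::dice_loss_grad(fw$p, y))
  numgrad <- function(set) {
    eps <- 1e-5
    lp <- dice_loss(aroiseg:::resunet_fwd(set(m, eps), x, train = TRUE)$p, y)
    lm <- dice_loss(aroiseg:::resunet_fwd(set(m, -eps), x, train = TRUE)$p, y)
    (lp - lm) / (2 * eps)
  }
  checks <- list(
    list(set = function(m, e) { m$units[[2]]$conv1$W[1, 1, 1, 1] <-
           m$units[[2]]$conv1$W[1, 1, 1, 1] + e; m },
         ana = g$units[[2]]$conv1$dW[1, 1, 1, 1]),
    list(set = function(m, e) { m$dec[[1]]$bn1$gamma[2] <-
           m$dec[[1]]$bn1$gamma[2] + e; m },
         ana = g$dec[[1]]$bn1$dgamma[2]),
    list(set = function(m, e) { m$units[[1]]$proj$W[1, 1, 1, 2] <-
           m$units[[1]]$proj$W[1, 1, 1, 2] + e; m },
         ana = g$units[[1]]$proj$dW[1, 1, 1, 2]),
    list(set = function(m, e) { m$head$b[1] <- m$head$b[1] + e; m },
         ana = g$head$db[1])
  )
  for (chk in checks) {
    expect_equal(numgrad(chk$set), chk$ana, tolerance = 1e-5)
  }
})

test_that("sigmoid output lies strictly in (0, 1)", {
  m <- build_resunet(resunet_spec(c(16, 16), c(4, 6)), seed = 3)
  p <- predict(m, array(rnorm(16 * 16 * 2), c(16, 16, 2)))
  expect_true(all(p > 0 & p < 1))
})

test_that("dice loss hits its endpoints and matches a brute-force evaluation", {
  t1 <- array((runif(32) > 0.5) * 1, c(4, 4, 2))
  expect_lt(dice_loss(t1, t1), 1e-6)
  expect_gt(dice_loss(1 - t1, t1), 1 - 1e-6)

  # uniform 0.5 prediction vs half-foreground truth, brute force per sample
  p <- array(0.5, c(4, 4, 2))
  t2 <- array(0, c(4, 4, 2)); t2[, 1:2, ] <- 1
  brute <- mean(vapply(1:2, function(i) {
    num <- 0; dp <- 0; dt <- 0
    for (a in 1:4) for (b in 1:4) {
      num <- num + 2 * p[a, b, i] * t2[a, b, i]
      dp <- dp + p[a, b, i]; dt <- dt + t2[a, b, i]
    }
    1 - num / (dp + dt + 1e-7)
  }, numeric(1)))
  expect_equal(dice_loss(p, t2), brute, tolerance = 1e-12)

  expect_error(dice_loss(array(0.5, c(2, 2, 1)), array(1, c(3, 3, 1))),
               "shapes differ")
})

test_that("dice loss equals 1 - DSC on binary predictions", {
  set.seed(21)
  for (i in 1:20) {
    a <- array((runif(60) > 0.5) * 1, c(5, 4, 3))
    b <- array((runif(60) > 0.5) * 1, c(5, 4, 3))
    per_sample <- vapply(1:3, function(k) {
      dsc(array(a[, , k], c(5, 4, 1)), array(b[, , k], c(5, 4, 1)))
    }, numeric(1))
    expect_equal(dice_loss(a, b), mean(1 - per_sample), tolerance = 1e-5)
  }
})

test_that("zero learning rate leaves the weights unchanged and training is seed-reproducible", {
  data <- make_blob_patches(8, c(16, 16), seed = 5)
  spec <- resunet_spec(c(16, 16), c(4, 6))
  m <- build_resunet(spec, seed = 4)
  fit0 <- train_resunet(m, data$patches, data$masks,
                        train_config(learning_rate = 1e-12, epochs = 1,
                                     seed = 1))
  expect_equal(fit0$model$units[[1]]$conv1$W, m$units[[1]]$conv1$W,
               tolerance = 1e-9)
  cfg <- train_config(learning_rate = 0.05, momentum = 0.9, epochs = 2,
                      seed = 3)
  f1 <- train_resunet(m, data$patches, data$masks, cfg)
  f2 <- train_resunet(m, data$patches, data$masks, cfg)
  expect_equal(f1$model$head$W, f2$model$head$W, tolerance = 1e-12)
  expect_equal(f1$history$train_loss, f2$history$train_loss,
               tolerance = 1e-12)
})

test_that("the network can overfit a single sample (capacity check)", {
  data <- make_blob_patches(1, c(16, 16), seed = 6)
  m <- build_resunet(resunet_spec(c(16, 16), c(6, 8)), seed = 5)
  fit <- train_resunet(m, data$patches, data$masks,
                       train_config(learning_rate = 0.1, momentum = 0.9,
                                    batch_size = 1, epochs = 40, seed = 2))
  expect_gt(tail(fit$history$train_dsc, 1), 0.98)
})

test_that("a trained-model segmenter honours shape, threshold and binarity", {
  m <- build_resunet(resunet_spec(c(16, 16), c(4, 6)), seed = 6)
  seg_all <- as_segmenter(m, threshold = 0)    # sigmoid > 0 everywhere
  patch <- matrix(runif(20 * 24), 20, 24)
  out <- seg_all(patch)
  expect_equal(dim(out), c(20, 24))
  expect_true(all(out == 1))
  seg_none <- as_segmenter(m, threshold = 1.01)
  expect_true(all(seg_none(patch) == 0))
})
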
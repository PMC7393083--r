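# literal double-loop directed Hausdorff over full foreground point sets
brute_directed_hd <- function(from, to, spacing) {
  a <- which(from != 0, arr.ind = TRUE) - 1
  b <- which(to != 0, arr.ind = TRUE) - 1
  worst <- 0
  for (i in seq_len(nrow(a))) {
    best <- Inf
    for (j in seq_len(nrow(b))) {
      d <- sqrt(sum(((a[i, ] - b[j, ]) * spacing)^2))
      best <- min(best, d)
    }
    worst <- max(worst, best)
  }
  worst
}

rand_mask <- function(d, p = 0.1) array((runif(prod(d)) < p) * 1L, d)

test_that("overlap metrics reproduce hand-computed cases", {
  d <- c(3, 4, 4)
  a <- array(0L, d); a[1, 1, 1:4] <- 1L                 # |a| = 4
  b <- array(0L, d); b[1, 1, 3:4] <- 1L; b[2, 2, 1:2] <- 1L  # |b| = 4, overlap 2
  expect_equal(dsc(a, b), 0.5)
  expect_equal(dsc(a, a), 1)
  disj <- array(0L, d); disj[3, 4, 1] <- 1L
  expect_equal(dsc(a, disj), 0)
  expect_equal(dsc(array(0L, d), array(0L, d)), 1)     # both-empty convention

  ref <- array(0L, d); ref[seq_len(10)] <- 1L          # |ref| = 10
  pred <- array(0L, d); pred[5:12] <- 1L               # |pred| = 8, overlap 6
  got <- sen_ppv(pred, ref)
  expect_equal(unname(got["sen"]), 0.6)
  expect_equal(unname(got["ppv"]), 0.75)

  sup <- a; sup[3, 3, 3] <- 1L                         # strict superset of a
  expect_equal(unname(sen_ppv(sup, a)["sen"]), 1)
  expect_lt(unname(sen_ppv(sup, a)["ppv"]), 1)
  expect_equal(unname(sen_ppv(a, sup)["ppv"]), 1)
  expect_lt(unname(sen_ppv(a, sup)["sen"]), 1)
})

test_that("Hausdorff distance reproduces hand cases and the directed form is asymmetric", {
  d <- c(6, 6, 6)
  a <- array(0L, d); a[1, 1, 1] <- 1L
  b <- array(0L, d); b[1, 4, 5] <- 1L                  # offsets (0, 3, 4)
  expect_equal(hausdorff_mm(a, b, spacing = c(1, 1, 1)), 5)

  expect_equal(hausdorff_mm(a, a, spacing = c(1, 1, 1)), 0)

  ab <- array(0L, d); ab[1, 1, 1] <- 1L; ab[1, 1, 6] <- 1L  # a plus point at 5
  expect_equal(hausdorff_directed_mm(a, ab, spacing = c(1, 1, 1)), 0)
  expect_equal(hausdorff_directed_mm(ab, a, spacing = c(1, 1, 1)), 5)
  expect_equal(hausdorff_mm(a, ab, spacing = c(1, 1, 1)), 5)

  empty <- array(0L, d)
  expect_true(is.na(hausdorff_mm(a, empty, spacing = c(1, 1, 1))))
})

test_that("the reduced-set Hausdorff equals the brute-force double loop", {
  set.seed(51)
  for (i in 1:25) {
    d <- c(sample(3:6, 1), sample(3:6, 1), sample(3:6, 1))
    spacing <- runif(3, 0.5, 3)
    a <- rand_mask(d, 0.25); b <- rand_mask(d, 0.25)
    if (sum(a) == 0 || sum(b) == 0) next
    expect_equal(hausdorff_directed_mm(a, b, spacing),
                 brute_directed_hd(a, b, spacing), tolerance = 1e-10)
    expect_equal(hausdorff_mm(a, b, spacing),
                 max(brute_directed_hd(a, b, spacing),
                     brute_directed_hd(b, a, spacing)), tolerance = 1e-10)
  }
})

test_that("DSC is the harmonic mean of SEN and PPV", {
  set.seed(52)
  for (i in 1:50) {
    d <- c(4, 5, 5)
    a <- rand_mask(d, 0.3); b <- rand_mask(d, 0.3)
    if (sum(a) == 0 || sum(b) == 0) next
    sp <- sen_ppv(a, b)
    if (sp["sen"] + sp["ppv"] == 0) {
      expect_equal(dsc(a, b), 0)
    } else {
      expect_equal(dsc(a, b),
                   2 * sp["sen"] * sp["ppv"] / (sp["sen"] + sp["ppv"]),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("metrics are invariant to axis permutation with permuted spacing", {
  set.seed(53)
  a <- rand_mask(c(4, 5, 6), 0.2); b <- rand_mask(c(4, 5, 6), 0.2)
  spacing <- c(2.5, 0.7, 0.7)
  perm <- c(3, 1, 2)
  ap <- aperm(a, perm); bp <- aperm(b, perm)
  expect_equal(dsc(a, b), dsc(ap, bp))
  expect_equal(sen_ppv(a, b), sen_ppv(ap, bp))
  expect_equal(hausdorff_mm(a, b, spacing),
               hausdorff_mm(ap, bp, spacing[perm]), tolerance = 1e-10)
})

test_that("evaluate_masks aggregates counts consistently", {
  set.seed(54)
  a <- rand_mask(c(4, 4, 4), 0.3); b <- rand_mask(c(4, 4, 4), 0.3)
  r <- evaluate_masks(mask_volume(a, c(1, 1, 1)), mask_volume(b, c(1, 1, 1)))
  expect_equal(r$tp + r$fn, sum(b))
  expect_equal(r$tp + r$fp, sum(a))
  expect_equal(r$dsc, 2 * r$tp / (2 * r$tp + r$fp + r$fn))
  expect_error(evaluate_masks(mask_volume(a, c(1, 1, 1)),
                              mask_volume(array(0L, c(3, 3, 3)), c(1, 1, 1))),
               "shapes differ")
})
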
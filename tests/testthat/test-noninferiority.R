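test_that("paired AUC test matches the brute-force placement oracle", {
  # hand-built 8-patient pairing with discordant reads
  la <- c(1, 1, 0, 0, 1, 0, 0, 1)
  lb <- c(1, 0, 1, 0, 0, 0, 1, 1)
  ref <- c(1, 1, 1, 0, 0, 0, 1, 0)
  pairs <- paired_predictions(la, lb, ref)
  res <- paired_auc_noninf(pairs, margin = 0.05)
  o <- oracle_paired_auc_z(la, lb, ref, margin = 0.05)
  expect_equal(res$delta_hat, o$delta, tolerance = 1e-12)
  expect_equal(res$SE_diff, o$se, tolerance = 1e-12)
  expect_equal(res$Z, o$z, tolerance = 1e-12)
  expect_equal(res$p_one_sided, pnorm(o$z, lower.tail = FALSE), tolerance = 1e-12)

  # a second random panel of small pairings
  set.seed(31)
  for (i in 1:25) {
    n <- sample(6:12, 1)
    ref <- c(1, 1, 0, 0, rbinom(n - 4, 1, 0.4))
    la <- rbinom(n, 1, 0.5)
    lb <- rbinom(n, 1, 0.5)
    res <- paired_auc_noninf(paired_predictions(la, lb, ref), margin = 0.05)
    o <- oracle_paired_auc_z(la, lb, ref, margin = 0.05)
    expect_equal(res$delta_hat, o$delta, tolerance = 1e-12)
    if (is.finite(res$Z)) expect_equal(res$SE_diff, o$se, tolerance = 1e-12)
  }
})

test_that("identical modalities are declared non-inferior by convention", {
  lab <- c(1, 0, 1, 0, 0, 1)
  ref <- c(1, 0, 1, 0, 1, 0)
  pairs <- paired_predictions(lab, lab, ref)
  res <- paired_auc_noninf(pairs)
  expect_equal(res$delta_hat, 0)
  expect_equal(res$SE_diff, 0)
  expect_equal(res$conclusion, "noninferior")
  expect_lt(res$p_one_sided, 1e-300)
  resf <- paired_f1_noninf(pairs, engine = "analytic")
  expect_equal(resf$delta_hat, 0)
  expect_equal(resf$conclusion, "noninferior")
})

test_that("paired AUC test rejects degenerate inputs", {
  expect_error(paired_auc_noninf(paired_predictions(c(1, 0), c(0, 1), c(1, 1))),
               "reference class")
  expect_error(paired_predictions(c(1, NA), c(0, 1), c(1, 0)), "complete")
  expect_error(paired_predictions(c(1, 2), c(0, 1), c(1, 0)), "binary")
})

test_that("analytic and bootstrap F1 variances agree on moderate samples", {
  set.seed(12)
  n <- 500
  ref <- rbinom(n, 1, 0.3)
  la <- ifelse(ref == 1, rbinom(n, 1, 0.75), rbinom(n, 1, 0.06))
  lb <- ifelse(ref == 1, rbinom(n, 1, 0.65), rbinom(n, 1, 0.10))
  pairs <- paired_predictions(la, lb, ref)
  an <- paired_f1_noninf(pairs, engine = "analytic")
  bo <- paired_f1_noninf(pairs, engine = "bootstrap", B_reps = 4000, seed = 77)
  expect_lt(abs(an$SE_diff - bo$SE_diff) / an$SE_diff, 0.15)
  expect_equal(an$delta_hat, bo$delta_hat)
})

test_that("bootstrap SE matches exhaustive enumeration on a 6-patient toy", {
  # one discordant case between the modalities
  la <- c(1, 1, 0, 0, 0, 1)
  lb <- c(1, 0, 0, 0, 0, 1)
  ref <- c(1, 1, 1, 0, 0, 0)
  pairs <- paired_predictions(la, lb, ref)
  exact_sd <- oracle_exhaustive_boot_sd(as.data.frame(pairs), function(d) {
    fa <- oracle_f1(d$label_a, d$reference)
    fb <- oracle_f1(d$label_b, d$reference)
    if (is.nan(fa) || is.nan(fb)) NA_real_ else fa - fb
  })
  boot <- bootstrap_paired(pairs, function(d) {
    fa <- oracle_f1(d$label_a, d$reference)
    fb <- oracle_f1(d$label_b, d$reference)
    if (is.nan(fa) || is.nan(fb)) NA_real_ else fa - fb
  }, B = 8000, seed = 4)
  expect_lt(abs(boot$se - exact_sd) / exact_sd, 0.06)
})

test_that("bootstrap is deterministic given seed and validates inputs", {
  set.seed(14)
  pairs <- paired_predictions(rbinom(30, 1, .5), rbinom(30, 1, .5), rbinom(30, 1, .4))
  stat <- function(d) mean(d$reference)
  b1 <- bootstrap_paired(pairs, stat, B = 500, seed = 9)
  b2 <- bootstrap_paired(pairs, stat, B = 500, seed = 9)
  expect_identical(b1, b2)
  expect_error(bootstrap_paired(pairs, stat, B = 50, seed = 1), "B_reps")
  # constant statistic -> SE 0
  expect_equal(bootstrap_paired(pairs, function(d) 1, B = 200, seed = 2)$se, 0)
  # SE of a binomial mean close to the closed form
  b3 <- bootstrap_paired(pairs, stat, B = 2000, seed = 10)
  p <- mean(pairs$reference)
  expect_lt(abs(b3$se - sqrt(p * (1 - p) / 30)) / sqrt(p * (1 - p) / 30), 0.10)
})

test_that("bootstrap leaves the caller's RNG state untouched", {
  set.seed(77)
  pairs <- paired_predictions(rbinom(20, 1, .5), rbinom(20, 1, .5),
                              rbinom(20, 1, .5))
  set.seed(123)
  before <- .Random.seed
  invisible(bootstrap_paired(pairs, function(d) mean(d$label_a), B = 200, seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("F1 test errors when F1 is undefined for a modality", {
  pairs <- paired_predictions(c(0, 0, 0, 0), c(1, 0, 1, 0), c(0, 0, 0, 0))
  expect_error(paired_f1_noninf(pairs), "F1 undefined")
})
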
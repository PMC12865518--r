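test_that("confusion cross-tabulates exactly and rejects bad input", {
  pred <- c("non_resectable", "resectable", "non_resectable", "resectable")
  ref <- c("non_resectable", "resectable", "resectable", "non_resectable")
  cc <- confusion(pred, ref)
  expect_equal(c(cc$tp, cc$fp, cc$fn, cc$tn), c(1, 1, 1, 1))
  expect_error(confusion(pred[1:3], ref), "equal length")
  expect_error(confusion(c(pred[1:3], "indeterminate"), ref), "indeterminate")
  expect_error(confusion(pred, c(ref[1:3], "excluded_inoperable")), "excluded_inoperable")
  # perfect agreement -> no errors
  cc2 <- confusion(ref, ref)
  expect_equal(c(cc2$fp, cc2$fn), c(0, 0))
})

test_that("point metrics honour the defining formulas on random counts", {
  set.seed(11)
  for (i in 1:50) {
    k <- sample(1:40, 4, replace = TRUE)
    cc <- confusion_counts(k[1], k[2], k[3], k[4])
    ms <- point_metrics(cc)
    e <- ms$estimates
    expect_equal(e[["se"]], k[1] / (k[1] + k[3]))
    expect_equal(e[["sp"]], k[4] / (k[4] + k[2]))
    expect_equal(e[["acc"]], (k[1] + k[4]) / sum(k))
    expect_equal(e[["auc"]], (e[["se"]] + e[["sp"]]) / 2)
    # F1 via the F-beta formula equals 2TP/(2TP+FP+FN) algebraically
    expect_equal(e[["f1"]], 2 * k[1] / (2 * k[1] + k[2] + k[3]))
    # every interval contains its point estimate
    for (m in c("se", "sp", "ppv", "npv", "acc", "auc")) {
      expect_gte(e[[m]], ms$ci[[m]][["lo"]] - 1e-12)
      expect_lte(e[[m]], ms$ci[[m]][["hi"]] + 1e-12)
    }
  }
})

test_that("zero-denominator metrics are undefined with a warning", {
  cc <- confusion_counts(0, 0, 0, 10)
  ms <- NULL
  w <- capture_warnings(ms <- point_metrics(cc))
  expect_true(all(grepl("undefined", w)) && length(w) >= 3)
  expect_true(is.na(ms$estimates[["se"]]))
  expect_true(is.na(ms$estimates[["ppv"]]))
  expect_true(is.na(ms$estimates[["f1"]]))
  expect_equal(ms$estimates[["sp"]], 1)
  expect_equal(ms$estimates[["acc"]], 1)
  expect_error(point_metrics(confusion_counts(0, 0, 0, 0)), "empty")
})

test_that("single-operating-point AUC equals the trapezoidal two-point ROC", {
  skip_if_not_installed("pROC")
  set.seed(99)
  for (i in 1:200) {
    k <- sample(1:30, 4, replace = TRUE)
    cc <- confusion_counts(k[1], k[2], k[3], k[4])
    score <- rep(c(1, 0, 1, 0), c(k[1], k[3], k[2], k[4]))
    ref <- rep(c(1, 1, 0, 0), c(k[1], k[3], k[2], k[4]))
    auc_pkg <- suppressWarnings(point_metrics(cc)$estimates[["auc"]])
    auc_roc <- suppressMessages(as.numeric(pROC::auc(pROC::roc(ref, score,
                                                               quiet = TRUE,
                                                               direction = "<"))))
    expect_equal(auc_pkg, auc_roc, tolerance = 1e-12)
  }
})

test_that("Wilson interval matches its closed form and edge case", {
  z <- qnorm(0.975)
  w <- wilson_interval(0, 10, 0.95)
  expect_equal(w[["lo"]], 0)
  expect_equal(w[["hi"]], z^2 / (10 + z^2))
  expect_error(wilson_interval(5, 0), "positive")
  expect_error(wilson_interval(11, 10), "0..n")
  # interval always within [0,1] and brackets p-hat
  set.seed(3)
  for (i in 1:100) {
    n <- sample(1:50, 1); x <- sample(0:n, 1)
    w <- wilson_interval(x, n)
    expect_true(w[["lo"]] >= 0 && w[["hi"]] <= 1)
    expect_true(w[["lo"]] <= x / n && x / n <= w[["hi"]])
  }
})

test_that("binary-score DeLong AUC interval matches the brute-force components", {
  cc <- confusion_counts(35, 7, 13, 112)
  ci <- auc_interval(cc, "delong_binary")
  # rebuild patient-level scores and feed the loop-based oracle
  score <- rep(c(1, 0, 1, 0), c(35, 13, 7, 112))
  ref <- rep(c(1, 1, 0, 0), c(35, 13, 7, 112))
  o <- oracle_delong(score, ref)
  n1 <- 48; n2 <- 119
  # population-variance form of the closed expression used by the package
  se2 <- (mean(o$v10^2) - mean(o$v10)^2) / n1 +
    (mean(o$v01^2) - mean(o$v01)^2) / n2
  a <- o$auc
  expect_equal(ci[["lo"]], a - qnorm(.975) * sqrt(se2), tolerance = 1e-10)
  expect_equal(ci[["hi"]], a + qnorm(.975) * sqrt(se2), tolerance = 1e-10)

  # perfect classifier: point 1.0, upper bound truncates to 1
  perfect <- confusion_counts(20, 0, 0, 30)
  ci2 <- auc_interval(perfect)
  expect_equal(ci2[["hi"]], 1)
  expect_error(auc_interval(confusion_counts(0, 5, 0, 5)), "non-empty")
})

test_that("rendered table reproduces the published ultrasound row", {
  tab <- render_metric_table(list(ultrasound = confusion_counts(35, 7, 13, 112)))
  expect_equal(tab$sens, "72.9 (59.0-83.4)")
  expect_equal(tab$spec, "94.1 (88.4-97.1)")
  expect_equal(tab$f1, "77.8")
  expect_equal(tab$f0.5, "81.0")
  expect_match(tab$auc, "^0\\.835")
})

test_that("half-up rounding differs from banker's rounding where it matters", {
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(1.5), 2)
  expect_equal(round_half_up(2.25, 1), 2.3)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(72.916667, 1), 72.9)
})
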
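test_that("simulation is a pure function of (config, seed)", {
  cfg <- sim_config(n_patients = 80, seed = 42)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$data, c2$data)
  # byte-identical CSV
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(c1, f1); write_cohort(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # different seed differs
  expect_false(identical(simulate_cohort(cfg, seed = 43)$data, c1$data))
})

test_that("generated cohorts satisfy every cohort invariant on a round trip", {
  cfg <- sim_config(n_patients = 150, seed = 3)
  co <- simulate_cohort(cfg)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, tmp)
  back <- read_cohort(tmp)          # strict validation must pass
  expect_identical(co$data, back$data)
  # r2_reason iff R2
  d <- back$data
  expect_true(all((d$outcome_r2_reason != "") == (d$outcome_residual == "R2")))
  # MRI criteria NA exactly where unavailable
  expect_true(all(is.na(d$mri_c1[d$mri_available == 0])))
  expect_true(all(!is.na(d$mri_c1[d$mri_available == 1])))
  # every truly non-resectable (non-inoperable R2) patient: reference derives
  refs <- reference_cohort(back)
  expect_true(all(refs %in% c("resectable", "non_resectable", "excluded_inoperable")))
})

test_that("perfect error-free assessors reproduce the truth (AUC 1)", {
  op <- list(us = c(se = 1, sp = 1), ct = c(se = 1, sp = 1),
             mri = c(se = 1, sp = 1), surg = c(se = 1, sp = 1))
  cfg <- sim_config(n_patients = 300, operating_points = op,
                    inoperable_fraction = 0, mri_missing_fraction = 0,
                    inter_modality_rho = 0, seed = 6)
  co <- simulate_cohort(cfg)
  ref <- reference_cohort(co)
  for (a in c("us", "ct", "mri", "surg")) {
    cc <- confusion(predict_cohort(co, a), ref)
    expect_equal(cc$fp + cc$fn, 0)
    ms <- point_metrics(cc)
    expect_equal(ms$estimates[["auc"]], 1)
  }
})

test_that("calibration hits the requested operating point and margins", {
  # moment-matched detection reproduces the patient-level operating point
  cfg <- sim_config(n_patients = 50000, inoperable_fraction = 0,
                    mri_missing_fraction = 0, inter_modality_rho = 0, seed = 9)
  co <- simulate_cohort(cfg)
  cc <- confusion(predict_cohort(co, "us"), reference_cohort(co))
  n1 <- cc$tp + cc$fn; n2 <- cc$tn + cc$fp
  expect_lt(abs(cc$tp / n1 - 35 / 48), 3 * sqrt(0.73 * 0.27 / n1))
  expect_lt(abs(cc$tn / n2 - 112 / 119), 3 * sqrt(0.94 * 0.06 / n2))
  # true site margins converge to the surgical-column targets
  truth_any <- mean(reference_cohort(co) == "non_resectable")
  expect_lt(abs(truth_any - 48 / 167), 3 * sqrt(0.287 * 0.713 / 50000))
})

test_that("calibrate_from_margins validates and inverts degenerate cases", {
  # single-site model with perfect detection: exact recovery
  op <- list(us = c(se = 1, sp = 1))
  cfg <- calibrate_from_margins(site_freqs = c(0.2, rep(0, 7)),
                                operating_points = op,
                                prevalence_nonresectable = 0.2,
                                n_patients = 10)
  # under truncation a single-site model involves the site almost surely
  expect_gt(cfg$site_probs[1], 0.99)
  expect_equal(cfg$detection$us$se_site, 1, tolerance = 1e-6)
  expect_equal(cfg$detection$us$fp_site, 0)
  # infeasible: perfect patient-level Se unreachable when per-site
  # sensitivity is capped at 0.5
  expect_error(
    sim_config(operating_points = list(us = c(se = 1, sp = 0.94)),
               max_site_se = 0.5),
    "infeasible operating point")
  # infeasible margins: site frequency above prevalence
  expect_error(calibrate_from_margins(c(0.5, rep(0.01, 7)),
                                      operating_points = list(us = c(se = .7, sp = .9)),
                                      prevalence_nonresectable = 0.3),
               "infeasible site margins")
})

test_that("fast paired-label path agrees with the full generator", {
  cfg <- sim_config(n_patients = 120, inoperable_fraction = 0,
                    mri_missing_fraction = 0, seed = 17)
  pairs <- resectability:::simulate_paired_labels(cfg, "us", "ct", seed = 17)
  co <- simulate_cohort(cfg, seed = 17)
  expect_equal(pairs$label_a,
               as.integer(predict_cohort(co, "us") == "non_resectable"))
  expect_equal(pairs$label_b,
               as.integer(predict_cohort(co, "ct") == "non_resectable"))
  expect_equal(pairs$reference,
               as.integer(reference_cohort(co) == "non_resectable"))
})

test_that("stronger inter-modality dependence shrinks the paired SE", {
  ses <- vapply(c(0, 0.45, 0.9), function(rho) {
    cfg <- sim_config(n_patients = 4000, inter_modality_rho = rho,
                      inoperable_fraction = 0, mri_missing_fraction = 0,
                      seed = 23)
    pairs <- resectability:::simulate_paired_labels(cfg, "us", "ct", seed = 23)
    paired_auc_noninf(pairs)$SE_diff
  }, numeric(1))
  expect_true(all(diff(ses) < 0))
})

test_that("config files round-trip through YAML and JSON", {
  args <- list(n_patients = 60, prevalence_nonresectable = 0.3,
               inter_modality_rho = 0.25, seed = 5,
               operating_points = list(us = list(se = 0.8, sp = 0.95),
                                       ct = list(se = 0.7, sp = 0.9),
                                       mri = list(se = 0.6, sp = 0.9),
                                       surg = list(se = 0.97, sp = 0.93)))
  fy <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(args, fy)
  cfg_y <- read_sim_config(fy)
  fj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(args, fj, auto_unbox = TRUE, digits = NA)
  cfg_j <- read_sim_config(fj)
  expect_equal(cfg_y$n_patients, 60)
  expect_equal(cfg_y$operating_points$us[["se"]], 0.8)
  expect_equal(unclass(cfg_y), unclass(cfg_j), tolerance = 1e-12)
  expect_identical(simulate_cohort(cfg_y)$data, simulate_cohort(cfg_j)$data)
})
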
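# Synthetic cohort generator: paired, correlated multimodal site assessments
# with surgical outcomes, an inoperable fraction and MRI missingness, so the
# whole pipeline is testable without access to patient-level study data.

# Default truth-margin targets: per-site involvement frequencies of the
# surgical-exploration reads of the modeled 242-patient study population
# (counts 57, 44, 7, 4, 4, 13, 11, 11 of 242).
default_site_margins <- function() {
  c(57, 44, 7, 4, 4, 13, 11, 11) / 242
}

# Default patient-level operating points (Se, Sp) of the four assessors in
# the 167-patient complete-case cohort this generator emulates.
default_operating_points <- function() {
  list(us = c(se = 35 / 48, sp = 112 / 119),
       ct = c(se = 30 / 48, sp = 105 / 119),
       mri = c(se = 26 / 48, sp = 107 / 119),
       surg = c(se = 47 / 48, sp = 110 / 119))
}

#' Construct a simulation configuration
#'
#' Parameterizes the synthetic cohort generator. Defaults emulate the study
#' conditions this package models: 167 patients, non-resectable prevalence
#' 48/167, per-site involvement probabilities calibrated so that true site
#' margins match the surgical-exploration frequencies of the modeled
#' population, per-assessor detection errors calibrated to the observed
#' patient-level operating points, an 18/242 inoperable fraction and 60/242
#' WB-DWI/MRI missingness.
#'
#' @param n_patients cohort size, default 167.
#' @param prevalence_nonresectable probability a patient's tumor is truly
#'   non-resectable, default 48/167.
#' @param site_probs per-criterion probability of true involvement given
#'   non-resectable disease (length 8). Defaults are calibrated from
#'   \code{site_margins}; resectable patients have no truly non-resectable
#'   site (the OR rule defines the class).
#' @param site_margins marginal per-site involvement frequencies used to
#'   calibrate \code{site_probs} when the latter is NULL.
#' @param operating_points named list (us, ct, mri, surg) of patient-level
#'   \code{c(se, sp)} targets to which per-site detection error is
#'   calibrated.
#' @param inter_modality_rho shared-latent correlation of detection errors
#'   across assessors, in [0, 1); default 0.5 (moderate positive dependence,
#'   as expected of modalities reading the same lesions).
#' @param inoperable_fraction fraction of patients overlaid as inoperable
#'   (R2 for frailty), default 18/242.
#' @param mri_missing_fraction fraction of patients without WB-DWI/MRI,
#'   default 60/242.
#' @param r0_r1_split probability an R0/R1 outcome is R0, default 145/162.
#' @param max_site_se cap on the per-site detection sensitivity used in
#'   calibration (default 1 = uncapped); operating points unreachable under
#'   the cap raise a diagnostic error.
#' @param seed RNG seed; generation is a pure function of (config, seed).
#' @return list of class \code{sim_config} with calibrated per-site
#'   parameters (\code{site_probs}, per-assessor \code{se_site} and
#'   \code{fp_site}).
#' @export
sim_config <- function(n_patients = 167,
                       prevalence_nonresectable = 48 / 167,
                       site_probs = NULL,
                       site_margins = default_site_margins(),
                       operating_points = default_operating_points(),
                       inter_modality_rho = 0.5,
                       inoperable_fraction = 18 / 242,
                       mri_missing_fraction = 60 / 242,
                       r0_r1_split = 145 / 162,
                       max_site_se = 1,
                       seed = 1) {
  stopifnot(n_patients >= 1,
            prevalence_nonresectable > 0, prevalence_nonresectable < 1,
            inter_modality_rho >= 0, inter_modality_rho < 1,
            inoperable_fraction >= 0, inoperable_fraction < 1,
            mri_missing_fraction >= 0, mri_missing_fraction <= 1,
            r0_r1_split >= 0, r0_r1_split <= 1)
  if (is.null(site_probs)) {
    site_probs <- calibrate_site_probs(site_margins, prevalence_nonresectable)
  }
  stopifnot(length(site_probs) == N_CRITERIA,
            all(site_probs >= 0), all(site_probs <= 1), any(site_probs > 0))
  detection <- lapply(operating_points, function(op) {
    calibrate_detection(op[["se"]], op[["sp"]], site_probs, max_site_se)
  })
  structure(list(
    n_patients = as.integer(n_patients),
    prevalence_nonresectable = prevalence_nonresectable,
    site_probs = site_probs,
    operating_points = operating_points,
    detection = detection,
    inter_modality_rho = inter_modality_rho,
    inoperable_fraction = inoperable_fraction,
    mri_missing_fraction = mri_missing_fraction,
    r0_r1_split = r0_r1_split,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Read a simulation configuration from a YAML or JSON file
#'
#' Accepts a file whose keys are the arguments of \code{\link{sim_config}};
#' missing keys take the documented defaults.
#'
#' @param path path to a .yaml/.yml or .json file.
#' @return a \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  args <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(args$operating_points)) {
    args$operating_points <- lapply(args$operating_points, function(op) {
      c(se = as.numeric(op[["se"]]), sp = as.numeric(op[["sp"]]))
    })
  }
  do.call(sim_config, args)
}

# Truncated-Bernoulli calibration of true per-site involvement: find r_j so
# that prevalence * P(site j involved | non-resectable, >=1 site involved)
# equals the requested marginal frequency m_j. Fixed point of
# r_j = (m_j / prev) * P(>=1 involved).
calibrate_site_probs <- function(site_margins, prevalence) {
  t_j <- site_margins / prevalence
  if (any(t_j > 1)) {
    stop("infeasible site margins: marginal frequency exceeds prevalence", call. = FALSE)
  }
  r <- pmin(t_j, 0.999)
  for (i in 1:200) {
    z <- 1 - prod(1 - r)
    r_new <- pmin(t_j * z, 1)
    if (max(abs(r_new - r)) < 1e-12) break
    r <- r_new
  }
  if (any(r >= 1)) stop("site-margin calibration did not converge", call. = FALSE)
  r
}

# Patient-level positive probability given the truth class, under common
# per-site detection sensitivity `se` and false-positive rate `fp`, with
# sites independent given class and the non-resectable site vector truncated
# to have at least one involved site.
patient_level_rates <- function(se, fp, site_probs) {
  k <- length(site_probs)
  p_none <- prod(1 - site_probs)         # untruncated P(no site involved)
  e0 <- prod((1 - site_probs) * (1 - fp) + site_probs * (1 - se))
  p_neg_given_nr <- (e0 - p_none * (1 - fp)^k) / (1 - p_none)
  c(se = 1 - p_neg_given_nr, sp = (1 - fp)^k)
}

# Solve common per-site (se, fp) so that the OR-aggregated patient-level
# operating point matches (se_target, sp_target) exactly under the site
# model (moment matching). `max_site_se` caps the attainable per-site
# sensitivity (1 = uncapped); a target beyond the cap's reach is diagnosed.
calibrate_detection <- function(se_target, sp_target, site_probs,
                                max_site_se = 1) {
  stopifnot(se_target > 0, se_target <= 1, sp_target > 0, sp_target <= 1,
            max_site_se > 0, max_site_se <= 1)
  fp <- 1 - sp_target^(1 / length(site_probs))
  se_max <- patient_level_rates(max_site_se, fp, site_probs)[["se"]]
  if (se_target > se_max + 1e-12) {
    stop(sprintf("infeasible operating point: patient-level Se %.3f exceeds the maximum %.3f attainable under the site model",
                 se_target, se_max), call. = FALSE)
  }
  f <- function(se) patient_level_rates(se, fp, site_probs)[["se"]] - se_target
  se <- stats::uniroot(f, c(0, max_site_se), tol = 1e-12)$root
  list(se_site = se, fp_site = fp)
}

#' Calibrate a simulation configuration from printed margins
#'
#' Inverts published marginal summaries into generator parameters: per-site
#' involvement frequencies become truth-model probabilities (truncated so
#' every non-resectable patient has at least one involved site), and
#' per-assessor patient-level operating points become common per-site
#' detection sensitivities and false-positive rates by moment matching of
#' the OR-aggregated detection probability (exact under the
#' conditional-independence site model). Infeasible operating points (e.g. a
#' patient-level sensitivity no per-site sensitivity can reach) raise a
#' diagnostic error.
#'
#' @param site_freqs marginal per-site involvement frequencies (length 8,
#'   proportions).
#' @param operating_points named list of per-assessor \code{c(se, sp)}.
#' @param ... further arguments passed to \code{\link{sim_config}}.
#' @return a \code{sim_config}.
#' @export
calibrate_from_margins <- function(site_freqs, operating_points, ...) {
  stopifnot(all(site_freqs >= 0), all(site_freqs <= 1))
  sim_config(site_margins = site_freqs, operating_points = operating_points,
             ...)
}

# Core draw: returns list of truth and per-assessor detection matrices.
# Shared latent W (per patient-site) plus independent noise induces the
# inter-modality correlation; thresholding at the conditional detection
# probability preserves each assessor's marginal operating point.
simulate_raw <- function(config) {
  n <- config$n_patients
  k <- N_CRITERIA
  truth_class <- stats::rbinom(n, 1, config$prevalence_nonresectable)
  truth_sites <- matrix(0L, n, k)
  nr <- which(truth_class == 1)
  if (length(nr) > 0) {
    m <- matrix(stats::rbinom(length(nr) * k, 1, rep(config$site_probs, each = length(nr))),
                length(nr), k)
    # truncate: every truly non-resectable patient has >= 1 involved site
    redo <- which(rowSums(m) == 0)
    while (length(redo) > 0) {
      m[redo, ] <- matrix(stats::rbinom(length(redo) * k, 1,
                                        rep(config$site_probs, each = length(redo))),
                          length(redo), k)
      redo <- redo[rowSums(m[redo, , drop = FALSE]) == 0]
    }
    truth_sites[nr, ] <- m
  }
  rho <- config$inter_modality_rho
  w <- matrix(stats::rnorm(n * k), n, k)
  detect <- lapply(config$detection, function(d) {
    q <- ifelse(truth_sites == 1L, d$se_site, d$fp_site)
    z <- sqrt(rho) * w + sqrt(1 - rho) * matrix(stats::rnorm(n * k), n, k)
    (stats::pnorm(z) < q) * 1L
  })
  list(truth_class = truth_class, truth_sites = truth_sites, detect = detect)
}

#' Simulate a synthetic cohort
#'
#' Draws, for each patient: a true resectability class; a true
#' site-involvement vector (non-resectable patients have at least one
#' involved site); per-assessor observed criteria through a shared
#' latent-Gaussian threshold model inducing the configured inter-modality
#' correlation; a surgical outcome consistent with the true class
#' (non-resectable -> R2 for tumor reasons; resectable -> R0/R1 mix) with an
#' inoperable overlay; and WB-DWI/MRI missingness. Deterministic given
#' (config, seed): the same configuration always yields a byte-identical
#' cohort CSV.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed optional override of \code{config$seed}.
#' @return a \code{cohort}.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    raw <- simulate_raw(config)
    n <- config$n_patients
    nr <- raw$truth_class == 1

    residual <- character(n)
    reason <- character(n)
    # R2 reason split among tumor-non-resectable: suboptimal after maximum
    # effort vs not feasible at laparoscopy, at the modeled study's 23:39 mix
    residual[nr] <- "R2"
    reason[nr] <- ifelse(stats::runif(sum(nr)) < 23 / 62,
                         "suboptimal_after_max_effort",
                         "not_feasible_at_laparoscopy")
    residual[!nr] <- ifelse(stats::runif(sum(!nr)) < config$r0_r1_split, "R0", "R1")

    inop <- stats::runif(n) < config$inoperable_fraction
    residual[inop] <- "R2"
    reason[inop] <- "inoperable"

    approach <- ifelse(reason == "not_feasible_at_laparoscopy", "laparoscopy",
                       "laparotomy")

    mri_missing <- stats::runif(n) < config$mri_missing_fraction

    df <- data.frame(
      patient_id = sprintf("S%04d", seq_len(n)),
      mri_available = as.integer(!mri_missing),
      outcome_residual = residual,
      outcome_r2_reason = reason,
      approach = approach,
      excl_flags = "",
      stringsAsFactors = FALSE
    )
    for (key in names(ASSESSORS)) {
      m <- raw$detect[[key]]
      if (key == "mri") m[mri_missing, ] <- NA_integer_
      colnames(m) <- criterion_cols(key)
      df <- cbind(df, as.data.frame(m))
    }
    new_cohort(df, provenance = sprintf(
      "simulate_cohort(n=%d, prev=%.3f, rho=%.2f, seed=%d)",
      n, config$prevalence_nonresectable, config$inter_modality_rho, seed))
  })
}

# Fast path for simulation experiments: paired binary patient-level labels
# for two assessors plus the true class, skipping cohort assembly, outcome
# overlay and missingness. Must agree with predict_cohort on the full
# generator given the same seed (tested).
simulate_paired_labels <- function(config, assessor_a = "us", assessor_b = "ct",
                                   seed = config$seed) {
  with_seed(seed, {
    raw <- simulate_raw(config)
    lab <- function(key) as.integer(rowSums(raw$detect[[key]]) > 0)
    paired_predictions(lab(assessor_key(assessor_a)),
                       lab(assessor_key(assessor_b)),
                       raw$truth_class)
  })
}

#' Type-I error and power experiment for the paired non-inferiority tests
#'
#' Monte-Carlo calibration harness: for each true AUC difference in
#' \code{true_delta_grid}, simulates \code{reps} paired cohorts in which
#' modality A's sensitivity is shifted by 2*delta relative to the base
#' operating point (so true AUC_A - AUC_B = delta), runs the paired AUC
#' non-inferiority test (and optionally the paired F1 test) on each, and
#' reports the rejection (non-inferiority) rate with its Monte-Carlo SE.
#'
#' @param config a \code{\link{sim_config}}; its \code{us} operating point is
#'   the base, and inoperable/missingness overlays are disabled for the
#'   experiment.
#' @param margin non-inferiority margin, default 0.05.
#' @param true_delta_grid numeric vector of true AUC differences (A - B).
#' @param reps replicates per grid point (>= 500).
#' @param seed master seed; replicate r of grid point g uses an independent
#'   substream.
#' @param alpha one-sided level, default 0.05.
#' @param include_f1 also run the paired F1 test (analytic engine) per
#'   replicate.
#' @return data frame with columns \code{true_delta}, \code{reps},
#'   \code{rejection_rate_auc}, \code{mc_se_auc} and, when requested,
#'   \code{rejection_rate_f1}, \code{mc_se_f1}.
#' @export
experiment_type1_power <- function(config, margin = 0.05,
                                   true_delta_grid = c(-0.05, 0),
                                   reps = 2000, seed = 1, alpha = 0.05,
                                   include_f1 = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (reps < 500) stop("reps must be at least 500", call. = FALSE)
  base <- config$operating_points
  rows <- lapply(seq_along(true_delta_grid), function(g) {
    delta <- true_delta_grid[g]
    # both modalities start from the same base operating point (modality A =
    # "us", modality B = "ct"); A's sensitivity is shifted by 2*delta so that
    # the true AUC difference A - B equals delta exactly
    op <- base
    op$ct <- base$us
    op$us <- c(se = base$us[["se"]] + 2 * delta, sp = base$us[["sp"]])
    if (op$us[["se"]] <= 0 || op$us[["se"]] > 1) {
      stop("true_delta shifts sensitivity outside (0, 1]", call. = FALSE)
    }
    cfg <- sim_config(
      n_patients = config$n_patients,
      prevalence_nonresectable = config$prevalence_nonresectable,
      site_probs = config$site_probs,
      operating_points = op,
      inter_modality_rho = config$inter_modality_rho,
      inoperable_fraction = 0, mri_missing_fraction = 0,
      seed = config$seed)
    rej_auc <- logical(reps)
    rej_f1 <- logical(reps)
    for (r in seq_len(reps)) {
      rep_seed <- (as.numeric(seed) * 1000003 + g * 10007 + r) %% 2147483629
      pairs <- simulate_paired_labels(cfg, "us", "ct", seed = rep_seed)
      res <- tryCatch(paired_auc_noninf(pairs, margin, alpha),
                      error = function(e) NULL)
      rej_auc[r] <- !is.null(res) && res$conclusion == "noninferior"
      if (include_f1) {
        resf <- tryCatch(paired_f1_noninf(pairs, margin, alpha, engine = "analytic"),
                         error = function(e) NULL)
        rej_f1[r] <- !is.null(resf) && resf$conclusion == "noninferior"
      }
    }
    out <- data.frame(true_delta = delta, reps = reps,
                      rejection_rate_auc = mean(rej_auc),
                      mc_se_auc = sqrt(mean(rej_auc) * (1 - mean(rej_auc)) / reps))
    if (include_f1) {
      out$rejection_rate_f1 <- mean(rej_f1)
      out$mc_se_f1 <- sqrt(mean(rej_f1) * (1 - mean(rej_f1)) / reps)
    }
    out
  })
  do.call(rbind, rows)
}
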
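# Paired non-inferiority tests: correlated single-operating-point AUCs via
# the binary-score DeLong variance decomposition with a shifted one-sided Z,
# and paired F1 scores via delta-method or bootstrap variance.

#' Assemble paired predictions
#'
#' @param label_a,label_b binary (0/1) patient-level predictions of
#'   modalities A and B on the same patients (1 = predicted non-resectable).
#' @param reference binary reference labels (1 = non-resectable).
#' @return object of class \code{paired_predictions} (a data frame).
#' @export
paired_predictions <- function(label_a, label_b, reference) {
  stopifnot(length(label_a) == length(label_b),
            length(label_a) == length(reference))
  df <- data.frame(label_a = as.integer(label_a), label_b = as.integer(label_b),
                   reference = as.integer(reference))
  if (anyNA(df)) stop("paired predictions must be complete cases", call. = FALSE)
  if (!all(unlist(df) %in% 0:1)) stop("labels must be binary 0/1", call. = FALSE)
  class(df) <- c("paired_predictions", "data.frame")
  df
}

#' Paired predictions of two assessors over a cohort
#'
#' Extracts complete-case paired binary predictions of two modalities against
#' the surgical-outcome reference. Inoperable patients must already have been
#' excluded; unassessed/indeterminate records are dropped with a message.
#'
#' @param cohort a \code{cohort}.
#' @param assessor_a,assessor_b assessor labels.
#' @return a \code{paired_predictions}.
#' @export
paired_from_cohort <- function(cohort, assessor_a, assessor_b) {
  pa <- predict_cohort(cohort, assessor_a)
  pb <- predict_cohort(cohort, assessor_b)
  ref <- reference_cohort(cohort)
  if (any(ref == "excluded_inoperable")) {
    stop("inoperable patients must be excluded before pairing", call. = FALSE)
  }
  ok <- !is.na(pa) & !is.na(pb) & pa != "indeterminate" & pb != "indeterminate"
  if (any(!ok)) {
    message(sprintf("paired_from_cohort: dropping %d incomplete record(s)", sum(!ok)))
  }
  paired_predictions(pa[ok] == "non_resectable", pb[ok] == "non_resectable",
                     ref[ok] == "non_resectable")
}

# DeLong placement values for a binary score: for each diseased subject the
# fraction of non-diseased subjects it out-ranks (ties count 1/2), and vice
# versa. Means of the placements are the empirical AUC.
delong_placements <- function(labels, reference) {
  d <- labels[reference == 1]
  nd <- labels[reference == 0]
  sp <- mean(nd == 0)
  se <- mean(d == 1)
  v10 <- ifelse(d == 1, sp + (1 - sp) / 2, sp / 2)
  v01 <- ifelse(nd == 0, se + (1 - se) / 2, se / 2)
  list(v10 = v10, v01 = v01, auc = (se + sp) / 2)
}

#' Paired AUC non-inferiority test
#'
#' Tests H0: AUC_A - AUC_B <= -margin against H1: AUC_A - AUC_B > -margin on
#' paired binary predictions. AUCs are single-operating-point
#' (balanced accuracy); the standard error of the difference comes from the
#' paired structural components of the DeLong decomposition (sample variance
#' of per-subject placement differences within each reference class, summed
#' across classes), which for two-valued scores has a closed form over the
#' 2x2x2 cross-classification. One-sided shifted Z test:
#' Z = (delta_hat + margin) / SE_diff.
#'
#' Identical predictions on every patient give SE_diff = 0 and delta_hat = 0;
#' by convention this degenerate case is declared non-inferior with the
#' p-value reported at the machine floor (a note is attached).
#'
#' @param pairs a \code{paired_predictions}.
#' @param margin non-inferiority margin on the AUC scale, default 0.05.
#' @param alpha one-sided significance level, default 0.05.
#' @return object of class \code{noninf_result}.
#' @export
paired_auc_noninf <- function(pairs, margin = 0.05, alpha = 0.05) {
  ref <- pairs$reference
  n1 <- sum(ref == 1)
  n2 <- sum(ref == 0)
  if (n1 < 2 || n2 < 2) {
    stop("need at least 2 subjects in each reference class", call. = FALSE)
  }
  pa <- delong_placements(pairs$label_a, ref)
  pb <- delong_placements(pairs$label_b, ref)
  delta <- pa$auc - pb$auc
  se_diff <- sqrt(stats::var(pa$v10 - pb$v10) / n1 +
                  stats::var(pa$v01 - pb$v01) / n2)
  finish_noninf("AUC", pa$auc, pb$auc, delta, margin, se_diff, alpha,
                variance_engine = "analytic")
}

f1_from_labels <- function(labels, reference) {
  tp <- sum(labels == 1 & reference == 1)
  fp <- sum(labels == 1 & reference == 0)
  fn <- sum(labels == 0 & reference == 1)
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

# Delta-method variance of F1_A - F1_B over the multinomial vector of the
# 8 joint cells (label_a x label_b x reference). F1 = 2x/(2x+y+z) with
# x = P(label=1, ref=1), y = P(label=1, ref=0), z = P(label=0, ref=1);
# dF1/dx = 2(y+z)/denom^2, dF1/dy = dF1/dz = -2x/denom^2.
f1_diff_variance_analytic <- function(pairs) {
  n <- nrow(pairs)
  cells <- expand.grid(a = 0:1, b = 0:1, r = 0:1)
  p <- mapply(function(a, b, r) {
    mean(pairs$label_a == a & pairs$label_b == b & pairs$reference == r)
  }, cells$a, cells$b, cells$r)
  grad_one <- function(lab) {
    x <- sum(p[cells[[lab]] == 1 & cells$r == 1])
    y <- sum(p[cells[[lab]] == 1 & cells$r == 0])
    z <- sum(p[cells[[lab]] == 0 & cells$r == 1])
    denom <- (2 * x + y + z)^2
    g <- numeric(nrow(cells))
    g[cells[[lab]] == 1 & cells$r == 1] <- 2 * (y + z) / denom
    g[cells[[lab]] == 1 & cells$r == 0] <- -2 * x / denom
    g[cells[[lab]] == 0 & cells$r == 1] <- -2 * x / denom
    g
  }
  g <- grad_one("a") - grad_one("b")
  (sum(p * g^2) - sum(p * g)^2) / n
}

#' Paired F1 non-inferiority test
#'
#' Tests H0: F1_A - F1_B <= -margin with a one-sided shifted Z test. The
#' variance of the F1 difference comes either from the delta method over the
#' multinomial vector of the 8 joint cells (\code{engine = "analytic"}) or
#' from patient-level paired bootstrap resampling
#' (\code{engine = "bootstrap"}, the default: more robust at small cell
#' counts).
#'
#' @param pairs a \code{paired_predictions}.
#' @param margin non-inferiority margin on the F1 scale, default 0.05.
#' @param alpha one-sided significance level, default 0.05.
#' @param engine \code{"bootstrap"} (default) or \code{"analytic"}.
#' @param B_reps bootstrap replicates (>= 100), default 2000.
#' @param seed RNG seed for the bootstrap engine.
#' @return object of class \code{noninf_result}.
#' @export
paired_f1_noninf <- function(pairs, margin = 0.05, alpha = 0.05,
                             engine = c("bootstrap", "analytic"),
                             B_reps = 2000, seed = 1) {
  engine <- match.arg(engine)
  f1_a <- f1_from_labels(pairs$label_a, pairs$reference)
  f1_b <- f1_from_labels(pairs$label_b, pairs$reference)
  if (is.na(f1_a) || is.na(f1_b)) {
    stop("F1 undefined for a modality (no predicted or actual positives)", call. = FALSE)
  }
  delta <- f1_a - f1_b
  if (engine == "analytic") {
    se_diff <- sqrt(max(0, f1_diff_variance_analytic(pairs)))
    extra <- list(variance_engine = "analytic")
  } else {
    boot <- bootstrap_paired(pairs, function(p) {
      fa <- f1_from_labels(p$label_a, p$reference)
      fb <- f1_from_labels(p$label_b, p$reference)
      fa - fb
    }, B = B_reps, seed = seed)
    se_diff <- boot$se
    extra <- list(variance_engine = "bootstrap", B_reps = B_reps, seed = seed,
                  boot_skipped = boot$skipped)
  }
  res <- finish_noninf("F1", f1_a, f1_b, delta, margin, se_diff, alpha,
                       variance_engine = extra$variance_engine)
  res[names(extra)] <- extra
  res
}

finish_noninf <- function(statistic_name, est_a, est_b, delta, margin, se_diff,
                          alpha, variance_engine) {
  note <- NULL
  if (se_diff > 0) {
    z <- (delta + margin) / se_diff
    p <- stats::pnorm(z, lower.tail = FALSE)
  } else if (delta + margin > 0) {
    z <- Inf
    p <- .Machine$double.xmin
    note <- "degenerate SE (identical or equally-placed predictions); non-inferiority declared by convention"
  } else {
    z <- -Inf
    p <- 1
    note <- "degenerate SE with delta at or below -margin"
  }
  structure(list(
    statistic_name = statistic_name,
    estimate_A = est_a, estimate_B = est_b,
    delta_hat = delta, margin = margin,
    SE_diff = se_diff, Z = z, p_one_sided = p, alpha = alpha,
    conclusion = if (p < alpha) "noninferior" else "not_demonstrated",
    variance_engine = variance_engine, note = note
  ), class = "noninf_result")
}

#' @export
print.noninf_result <- function(x, ...) {
  cat(sprintf("<noninf_result> %s: A=%.3f B=%.3f delta=%+.3f (margin %.2f)\n",
              x$statistic_name, x$estimate_A, x$estimate_B, x$delta_hat, x$margin))
  cat(sprintf("  Z=%.3f one-sided p=%s -> %s [%s variance]\n", x$Z,
              format.pval(x$p_one_sided, digits = 3), x$conclusion,
              x$variance_engine))
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Patient-level paired bootstrap
#'
#' Resamples patients (rows) with replacement, recomputes a scalar statistic
#' on each resample, and summarizes the resample distribution. Resamples on
#' which the statistic is NA (e.g. F1 with no positives drawn) are skipped
#' and counted. Deterministic given \code{seed}; the caller's RNG state is
#' untouched.
#'
#' @param pairs a \code{paired_predictions} (or any data frame of patients).
#' @param statistic function of a resampled data frame returning a scalar.
#' @param B number of resamples (>= 100).
#' @param seed RNG seed.
#' @param confidence level for the percentile interval, default 0.95.
#' @return list with \code{se}, \code{ci} (percentile), \code{skipped},
#'   \code{B}, \code{values}.
#' @export
bootstrap_paired <- function(pairs, statistic, B = 2000, seed = 1,
                             confidence = 0.95) {
  if (B < 100) stop("B_reps < 100 rejected", call. = FALSE)
  n <- nrow(pairs)
  values <- with_seed(seed, {
    vapply(seq_len(B), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      statistic(pairs[idx, , drop = FALSE])
    }, numeric(1))
  })
  ok <- !is.na(values)
  if (!any(ok)) stop("statistic NA on every resample", call. = FALSE)
  alpha2 <- (1 - confidence) / 2
  list(se = stats::sd(values[ok]),
       ci = stats::quantile(values[ok], c(alpha2, 1 - alpha2), names = FALSE),
       skipped = sum(!ok), B = B, values = values)
}
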
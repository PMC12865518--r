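# Confusion-matrix construction and single-operating-point accuracy metrics
# with confidence intervals. Positive class throughout = non_resectable.

#' Construct confusion counts
#'
#' @param tp,fp,fn,tn non-negative integer counts; positive class is
#'   non-resectable disease.
#' @return object of class \code{confusion_counts}.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  counts <- as.integer(counts)
  structure(list(tp = counts[1], fp = counts[2], fn = counts[3], tn = counts[4]),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d FN=%d TN=%d (n=%d, positives=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn, x$tp + x$fn))
  invisible(x)
}

#' Cross-tabulate predictions against reference labels
#'
#' @param predictions character vector of \code{"resectable"} /
#'   \code{"non_resectable"} patient-level predictions.
#' @param references character vector of the same length of reference labels.
#'   Indeterminate predictions and inoperable-excluded references must have
#'   been removed upstream; encountering one is an error.
#' @return a \code{confusion_counts}.
#' @export
confusion <- function(predictions, references) {
  if (length(predictions) != length(references)) {
    stop("predictions and references must have equal length", call. = FALSE)
  }
  if (any(is.na(predictions)) || any(predictions == "indeterminate")) {
    stop("indeterminate/missing predictions must be removed upstream", call. = FALSE)
  }
  if (any(is.na(references)) || any(references == "excluded_inoperable")) {
    stop("excluded_inoperable references must be removed upstream", call. = FALSE)
  }
  stopifnot(all(predictions %in% c("resectable", "non_resectable")),
            all(references %in% c("resectable", "non_resectable")))
  pos_p <- predictions == "non_resectable"
  pos_r <- references == "non_resectable"
  confusion_counts(tp = sum(pos_p & pos_r), fp = sum(pos_p & !pos_r),
                   fn = sum(!pos_p & pos_r), tn = sum(!pos_p & !pos_r))
}

#' Confusion counts of one assessor over a cohort
#'
#' Convenience wrapper: computes patient-level predictions and the
#' surgical-outcome reference over a cohort, drops records the assessor did
#' not examine or whose prediction is indeterminate (with a message giving the
#' count), and cross-tabulates. Inoperable patients must already have been
#' excluded.
#'
#' @param cohort a \code{cohort}.
#' @param assessor assessor label.
#' @return a \code{confusion_counts}.
#' @export
confusion_cohort <- function(cohort, assessor) {
  pred <- predict_cohort(cohort, assessor)
  ref <- reference_cohort(cohort)
  drop <- is.na(pred) | pred == "indeterminate"
  if (any(drop)) {
    message(sprintf("confusion_cohort(%s): dropping %d unassessed/indeterminate record(s)",
                    assessor_key(assessor), sum(drop)))
  }
  confusion(pred[!drop], ref[!drop])
}

#' F-beta score from precision and recall
#'
#' \eqn{F_\beta = (1+\beta^2) \cdot PPV \cdot Se / (\beta^2 \cdot PPV + Se)}.
#' F1 weights precision and recall equally; F0.5 up-weights precision.
#'
#' @param ppv precision (positive predictive value).
#' @param se recall (sensitivity).
#' @param beta weight; may be a vector.
#' @return numeric vector of the same length as \code{beta}.
#' @export
fbeta_score <- function(ppv, se, beta = 1) {
  if (is.na(ppv) || is.na(se)) return(rep(NA_real_, length(beta)))
  denom <- beta^2 * ppv + se
  ifelse(denom == 0, NA_real_, (1 + beta^2) * ppv * se / denom)
}

#' Wilson score interval for a binomial proportion
#'
#' @param successes number of successes (0..n).
#' @param n number of trials (> 0).
#' @param confidence confidence level, default 0.95.
#' @return numeric vector \code{c(lo, hi)}, both in [0, 1] and bracketing
#'   \code{successes/n}.
#' @export
wilson_interval <- function(successes, n, confidence = 0.95) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (successes < 0 || successes > n) stop("successes must lie in 0..n", call. = FALSE)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # at the boundaries the score bound is exactly 0 resp. 1; avoid float dust
  lo <- if (successes == 0) 0 else max(0, center - half)
  hi <- if (successes == n) 1 else min(1, center + half)
  c(lo = lo, hi = hi)
}

#' Clopper-Pearson exact interval (alternative proportion CI)
#'
#' Offered as an option; the package default is the Wilson score interval,
#' which reproduces the CIs printed in the tables this pipeline emulates.
#'
#' @inheritParams wilson_interval
#' @return numeric vector \code{c(lo, hi)}.
#' @export
clopper_pearson_interval <- function(successes, n, confidence = 0.95) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  ci <- stats::binom.test(successes, n, conf.level = confidence)$conf.int
  c(lo = ci[1], hi = ci[2])
}

#' Confidence interval for a single-operating-point AUC
#'
#' The AUC of a binary (single-threshold) test is balanced accuracy,
#' \eqn{(Se+Sp)/2}. The default \code{"delong_binary"} method applies the
#' DeLong variance decomposition, which for two-valued scores reduces to
#' \eqn{SE^2 = [Se(1-Se)/n_1 + Sp(1-Sp)/n_2]/4} with \eqn{n_1} diseased and
#' \eqn{n_2} non-diseased; \code{"hanley_mcneil"} uses the Hanley-McNeil SE
#' with \eqn{Q_1 = A/(2-A)}, \eqn{Q_2 = 2A^2/(1+A)}. Normal interval,
#' truncated to [0, 1].
#'
#' @param counts a \code{confusion_counts}.
#' @param method \code{"delong_binary"} (default) or \code{"hanley_mcneil"}.
#' @param confidence confidence level, default 0.95.
#' @return numeric vector \code{c(lo, hi)}.
#' @export
auc_interval <- function(counts, method = c("delong_binary", "hanley_mcneil"),
                         confidence = 0.95) {
  method <- match.arg(method)
  n1 <- counts$tp + counts$fn
  n2 <- counts$tn + counts$fp
  if (n1 == 0 || n2 == 0) stop("both reference classes must be non-empty", call. = FALSE)
  se <- counts$tp / n1
  sp <- counts$tn / n2
  a <- (se + sp) / 2
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  se_auc <- switch(method,
    delong_binary = sqrt((se * (1 - se) / n1 + sp * (1 - sp) / n2) / 4),
    hanley_mcneil = {
      q1 <- a / (2 - a)
      q2 <- 2 * a^2 / (1 + a)
      sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n2 - 1) * (q2 - a^2)) / (n1 * n2))
    })
  c(lo = max(0, a - z * se_auc), hi = min(1, a + z * se_auc))
}

#' All point metrics with confidence intervals from confusion counts
#'
#' Computes sensitivity, specificity, PPV, NPV, accuracy, F-beta scores and
#' the single-operating-point AUC = (Se+Sp)/2, with Wilson score intervals
#' for the proportions and a binary-score DeLong interval for the AUC.
#' Zero-denominator metrics are returned as \code{NA} with a warning. AUC
#' intervals are method-dependent for single-threshold tests and are flagged
#' as such in rendered reports.
#'
#' @param counts a \code{confusion_counts}.
#' @param betas F-score weights, default \code{c(1, 0.5)}.
#' @param confidence confidence level, default 0.95.
#' @param proportion_method \code{"wilson"} (default) or
#'   \code{"clopper_pearson"}.
#' @param auc_method passed to \code{\link{auc_interval}}.
#' @return object of class \code{metric_set}: a list with elements
#'   \code{estimates} (named numeric), \code{ci} (named list of
#'   \code{c(lo, hi)}), \code{counts}, and the methods used.
#' @export
point_metrics <- function(counts, betas = c(1, 0.5), confidence = 0.95,
                          proportion_method = c("wilson", "clopper_pearson"),
                          auc_method = c("delong_binary", "hanley_mcneil")) {
  proportion_method <- match.arg(proportion_method)
  auc_method <- match.arg(auc_method)
  n1 <- counts$tp + counts$fn
  n2 <- counts$tn + counts$fp
  npos <- counts$tp + counts$fp
  nneg <- counts$tn + counts$fn
  total <- n1 + n2
  if (total == 0) stop("empty confusion table", call. = FALSE)

  ratio <- function(num, den, name) {
    if (den == 0) {
      warning("metric ", name, " undefined (zero denominator)", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  est <- c(
    se = ratio(counts$tp, n1, "Se"),
    sp = ratio(counts$tn, n2, "Sp"),
    ppv = ratio(counts$tp, npos, "PPV"),
    npv = ratio(counts$tn, nneg, "NPV"),
    acc = (counts$tp + counts$tn) / total
  )
  fb <- vapply(betas, function(b) {
    v <- fbeta_score(est[["ppv"]], est[["se"]], b)
    if (is.na(v)) warning("metric F", b, " undefined", call. = FALSE)
    v
  }, numeric(1))
  names(fb) <- paste0("f", sub("\\.?0+$", "", format(betas)))
  auc <- if (n1 > 0 && n2 > 0) (est[["se"]] + est[["sp"]]) / 2 else NA_real_
  est <- c(est, fb, auc = auc)

  prop_ci <- function(x, n) {
    if (n == 0) return(c(lo = NA_real_, hi = NA_real_))
    if (proportion_method == "wilson") wilson_interval(x, n, confidence)
    else clopper_pearson_interval(x, n, confidence)
  }
  ci <- list(
    se = prop_ci(counts$tp, n1),
    sp = prop_ci(counts$tn, n2),
    ppv = prop_ci(counts$tp, npos),
    npv = prop_ci(counts$tn, nneg),
    acc = prop_ci(counts$tp + counts$tn, total),
    auc = if (n1 > 0 && n2 > 0) auc_interval(counts, auc_method, confidence)
          else c(lo = NA_real_, hi = NA_real_)
  )
  structure(list(estimates = est, ci = ci, counts = counts,
                 confidence = confidence,
                 proportion_method = proportion_method,
                 auc_method = auc_method),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat("<metric_set>\n")
  for (m in names(x$estimates)) {
    v <- x$estimates[[m]]
    ci <- x$ci[[m]]
    if (m == "auc") {
      cat(sprintf("  %-4s %s", m,
                  ifelse(is.na(v), "NA", formatC(round_half_up(v, 3), format = "f", digits = 3))))
    } else {
      cat(sprintf("  %-4s %s%%", m, fmt_pct(v)))
    }
    if (!is.null(ci) && !any(is.na(ci))) {
      if (m == "auc") {
        cat(sprintf(" (%.3f-%.3f)", round_half_up(ci[["lo"]], 3), round_half_up(ci[["hi"]], 3)))
      } else {
        cat(sprintf(" (%s-%s)", fmt_pct(ci[["lo"]]), fmt_pct(ci[["hi"]])))
      }
    }
    cat("\n")
  }
  invisible(x)
}

#' Render a performance table across assessors
#'
#' Builds the study-style performance table (one row per assessor; columns:
#' AUC with CI, TN/FN/FP/TP with percentages of the cohort, then Se, Sp, PPV,
#' NPV, accuracy, F1 and F0.5, each with its CI). All numbers come from one
#' rounding policy: percentages half-up at 1 decimal, AUC at 3 decimals.
#'
#' @param counts_list named list of \code{confusion_counts}, one per assessor.
#' @param ... passed to \code{\link{point_metrics}}.
#' @return data frame of formatted strings, one row per assessor.
#' @export
render_metric_table <- function(counts_list, ...) {
  rows <- lapply(names(counts_list), function(label) {
    ct <- counts_list[[label]]
    ms <- point_metrics(ct, ...)
    total <- ct$tp + ct$fp + ct$fn + ct$tn
    cnt <- function(k) sprintf("%d (%s)", ct[[k]], fmt_pct(ct[[k]] / total))
    pct_ci <- function(m) {
      sprintf("%s (%s-%s)", fmt_pct(ms$estimates[[m]]),
              fmt_pct(ms$ci[[m]][["lo"]]), fmt_pct(ms$ci[[m]][["hi"]]))
    }
    # F-score CIs: Wilson on the equivalent proportion scale is not defined;
    # report the point estimate only (interval estimation for F-scores is
    # handled by the bootstrap engine in the non-inferiority module).
    data.frame(
      procedure = label,
      auc = sprintf("%.3f (%.3f-%.3f)", round_half_up(ms$estimates[["auc"]], 3),
                    round_half_up(ms$ci$auc[["lo"]], 3), round_half_up(ms$ci$auc[["hi"]], 3)),
      tn = cnt("tn"), fn = cnt("fn"), fp = cnt("fp"), tp = cnt("tp"),
      sens = pct_ci("se"), spec = pct_ci("sp"),
      ppv = pct_ci("ppv"), npv = pct_ci("npv"), accuracy = pct_ci("acc"),
      f1 = fmt_pct(ms$estimates[["f1"]]),
      f0.5 = fmt_pct(ms$estimates[["f0.5"]]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
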
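# Obuchowski-McClish sample-size calculation for non-inferiority comparison
# of two correlated AUCs under the binormal model.

#' Sample-size specification for a correlated-AUC non-inferiority design
#'
#' @param auc_both planning AUC assumed common to both tests (0.5, 1).
#' @param margin non-inferiority margin on the AUC scale, default 0.05.
#' @param alpha one-sided significance level, default 0.05.
#' @param power target power, default 0.90.
#' @param rho correlation between the two tests' AUC estimates in [0, 1).
#'   Paired same-patient designs of two imaging modalities reading the same
#'   anatomy typically sit well above independence; default 0.5.
#' @param ratio allocation ratio of non-diseased to diseased patients;
#'   default 119/48, the observed class balance of the complete-case study
#'   cohort this package models.
#' @return list of class \code{samplesize_spec}.
#' @export
samplesize_spec <- function(auc_both = 0.78, margin = 0.05, alpha = 0.05,
                            power = 0.90, rho = 0.5, ratio = 119 / 48) {
  if (auc_both <= 0.5 || auc_both >= 1) stop("auc_both must lie in (0.5, 1)", call. = FALSE)
  if (margin <= 0) stop("margin must be positive", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  if (ratio <= 0) stop("ratio must be positive", call. = FALSE)
  if (margin >= auc_both - 0.5) {
    warning("margin is as large as the distance of the planning AUC from chance",
            call. = FALSE)
  }
  structure(list(auc_both = auc_both, margin = margin, alpha = alpha,
                 power = power, rho = rho, ratio = ratio),
            class = "samplesize_spec")
}

#' Binormal AUC variance function of Obuchowski-McClish
#'
#' V(A) such that Var(AUC_hat) ~ V(A)/n1 with n1 diseased subjects and
#' ratio R non-diseased per diseased, under the binormal model with equal
#' binormal slopes: with a = qnorm(A) * sqrt(2),
#' V(A) = 0.0099 exp(-a^2/2) * (5a^2 + 8 + (a^2 + 8)/R).
#'
#' @param auc AUC in (0.5, 1).
#' @param ratio non-diseased-to-diseased allocation ratio R.
#' @return variance function value.
#' @export
om_variance <- function(auc, ratio = 1) {
  a <- stats::qnorm(auc) * sqrt(2)
  0.0099 * exp(-a^2 / 2) * (5 * a^2 + 8 + (a^2 + 8) / ratio)
}

#' Required total sample size for a correlated-AUC non-inferiority design
#'
#' Number of diseased subjects
#' n1 = (z_{1-alpha} + z_{1-beta})^2 * 2 V(A) (1 - rho) / margin^2,
#' scaled to total patients via the allocation ratio and rounded up.
#'
#' @param spec a \code{\link{samplesize_spec}}.
#' @return integer total number of patients (ceiling); attributes
#'   \code{n_diseased} and \code{variance} carry the components.
#' @export
required_n <- function(spec) {
  stopifnot(inherits(spec, "samplesize_spec"))
  v <- om_variance(spec$auc_both, spec$ratio)
  zsum <- stats::qnorm(1 - spec$alpha) + stats::qnorm(spec$power)
  n1 <- zsum^2 * 2 * v * (1 - spec$rho) / spec$margin^2
  total <- as.integer(ceiling(n1 * (1 + spec$ratio)))
  attr(total, "n_diseased") <- ceiling(n1)
  attr(total, "variance") <- v
  total
}

#' Achieved power at a given total sample size
#'
#' Inverse of \code{\link{required_n}}:
#' z_beta = sqrt(n1 * margin^2 / (2 V(A) (1 - rho))) - z_{1-alpha},
#' power = pnorm(z_beta), with n1 = n / (1 + ratio) diseased subjects.
#'
#' @param spec a \code{\link{samplesize_spec}}.
#' @param n total number of patients (>= 4).
#' @return achieved power in (0, 1).
#' @export
power_at_n <- function(spec, n) {
  stopifnot(inherits(spec, "samplesize_spec"))
  if (n < 4) stop("n must be at least 4", call. = FALSE)
  v <- om_variance(spec$auc_both, spec$ratio)
  n1 <- n / (1 + spec$ratio)
  zb <- sqrt(n1 * spec$margin^2 / (2 * v * (1 - spec$rho))) -
    stats::qnorm(1 - spec$alpha)
  stats::pnorm(zb)
}
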
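# Independent oracles and shared tiny fixtures used across the suite.

# Brute-force DeLong structural components for arbitrary scores: explicit
# double loops over all (diseased, non-diseased) pairs. Independent of the
# closed-form placement path in the package.
oracle_delong <- function(scores, reference) {
  d <- scores[reference == 1]
  nd <- scores[reference == 0]
  v10 <- vapply(d, function(x) mean((nd < x) + 0.5 * (nd == x)), numeric(1))
  v01 <- vapply(nd, function(y) mean((d > y) + 0.5 * (d == y)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

oracle_paired_auc_z <- function(la, lb, ref, margin) {
  a <- oracle_delong(la, ref)
  b <- oracle_delong(lb, ref)
  n1 <- sum(ref == 1)
  n2 <- sum(ref == 0)
  se <- sqrt(stats::var(a$v10 - b$v10) / n1 + stats::var(a$v01 - b$v01) / n2)
  list(delta = a$auc - b$auc, se = se, z = (a$auc - b$auc + margin) / se)
}

oracle_f1 <- function(lab, ref) {
  tp <- sum(lab == 1 & ref == 1)
  2 * tp / (2 * tp + sum(lab == 1 & ref == 0) + sum(lab == 0 & ref == 1))
}

# Exact SD of a statistic over the full bootstrap-resample distribution of a
# tiny data set: enumerates all n^n equally likely ordered resamples.
oracle_exhaustive_boot_sd <- function(df, statistic) {
  n <- nrow(df)
  grid <- do.call(expand.grid, rep(list(seq_len(n)), n))
  vals <- apply(as.matrix(grid), 1, function(idx) statistic(df[idx, , drop = FALSE]))
  vals <- vals[!is.na(vals)]   # NA resamples are skipped, as in the package
  sqrt(mean((vals - mean(vals))^2))
}

# A small deterministic cohort data frame with every schema column, built in
# code (no fixture file): n patients, all assessors assessed, all-absent
# criteria unless overridden.
make_cohort_df <- function(n, mri_available = 1L) {
  df <- data.frame(
    patient_id = sprintf("T%03d", seq_len(n)),
    mri_available = as.integer(rep_len(mri_available, n)),
    outcome_residual = "R0",
    outcome_r2_reason = "",
    approach = "laparotomy",
    excl_flags = "",
    stringsAsFactors = FALSE
  )
  for (key in c("us", "ct", "mri", "surg")) {
    for (j in 1:8) df[[paste0(key, "_c", j)]] <- 0L
  }
  for (j in 1:8) df[[paste0("mri_c", j)]][df$mri_available == 0L] <- NA_integer_
  df
}

fixture_242 <- function() {
  apply_eligibility(read_cohort(counts_fixture_path()))$cohort
}
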
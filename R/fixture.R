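# Deterministic counts fixture: a 279-row synthetic cohort constructed so
# that every marginal tally (cohort flow, outcome distribution, per-site
# involvement frequencies, per-modality confusion counts in both analysis
# cohorts) reproduces the printed counts of the multicenter study this
# package models. Joint distributions beyond those margins are arbitrary and
# filled deterministically; the fixture is synthetic, not patient data.

#' Published per-modality confusion counts
#'
#' The printed patient-level confusion counts of the modeled study, used as
#' fixed inputs throughout the test-suite and analyses: the 224-patient
#' cohort (inoperable excluded) for ultrasound, CT and surgical exploration,
#' and the 167-patient complete-case subcohort for all four assessors.
#'
#' @return data frame with columns \code{cohort} (224 or 167),
#'   \code{assessor}, \code{tp}, \code{fn}, \code{fp}, \code{tn}.
#' @export
published_confusion <- function() {
  data.frame(
    cohort = c(224, 224, 224, 167, 167, 167, 167),
    assessor = c("us", "ct", "surg", "us", "ct", "mri", "surg"),
    tp = c(40, 38, 59, 35, 30, 26, 47),
    fn = c(22, 24, 3, 13, 18, 22, 1),
    fp = c(9, 16, 10, 7, 14, 12, 9),
    tn = c(153, 146, 152, 112, 105, 107, 110),
    stringsAsFactors = FALSE
  )
}

#' Published per-site involvement counts
#'
#' Printed counts of patients scored as involved at each of the eight sites
#' by each assessor, plus the derived "criterion 1 and/or 2" and
#' "any of 1-8" rows, over the 242-patient analysis population
#' (182 for WB-DWI/MRI).
#'
#' @return named list with per-assessor list(counts, n12, any, n).
#' @export
published_site_counts <- function() {
  list(
    us = list(counts = c(32, 33, 3, 2, 3, 6, 9, 7), n12 = 44, any = 55, n = 242),
    ct = list(counts = c(30, 17, 10, 6, 3, 12, 16, 16), n12 = 35, any = 58, n = 242),
    mri = list(counts = c(15, 13, 5, 1, 3, 8, 16, 16), n12 = 21, any = 44, n = 182),
    surg = list(counts = c(57, 44, 7, 4, 4, 13, 11, 11), n12 = 68, any = 78, n = 242)
  )
}

# Distribute per-criterion presence indicators over the positive patients of
# one assessor so that column sums equal `counts`, the "1 and/or 2" tally
# equals `n12`, and every positive patient carries at least one criterion.
# Deterministic greedy fill; returns an n_pos x 8 0/1 matrix.
fill_criteria <- function(n_pos, counts, n12) {
  stopifnot(n_pos >= n12, counts[1] <= n12, counts[2] <= n12)
  both <- counts[1] + counts[2] - n12
  stopifnot(both >= 0)
  m <- matrix(0L, n_pos, N_CRITERIA)
  if (both > 0) m[seq_len(both), 1:2] <- 1L
  if (counts[1] > both) m[(both + 1):counts[1], 1] <- 1L
  if (n12 > counts[1]) m[(counts[1] + 1):n12, 2] <- 1L
  # cover the positives without criterion 1/2 using criteria 3..8 in order
  remaining <- counts[3:8]
  uncovered <- if (n_pos > n12) (n12 + 1):n_pos else integer(0)
  j <- 1L
  for (i in uncovered) {
    while (j <= 6L && remaining[j] == 0L) j <- j + 1L
    if (j > 6L) stop("not enough criterion-3..8 presences to cover all positives")
    m[i, j + 2L] <- 1L
    remaining[j] <- remaining[j] - 1L
  }
  # park leftover presences on patients not already carrying that criterion
  for (jj in 1:6) {
    col <- jj + 2L
    if (remaining[jj] > 0L) {
      free <- which(m[, col] == 0L)
      stopifnot(length(free) >= remaining[jj])
      m[free[seq_len(remaining[jj])], col] <- 1L
      remaining[jj] <- 0L
    }
  }
  stopifnot(identical(as.integer(colSums(m)), as.integer(counts)),
            all(rowSums(m) >= 1L))
  m
}

#' Build the counts fixture cohort
#'
#' Constructs the deterministic 279-record fixture: 37 records carry
#' exclusion flags (distributed across the seven exclusion codes; the
#' per-code breakdown is arbitrary), 242 are analyzable with outcomes
#' R0/R1/R2 = 145/17/80 (R2 reasons 23/39/18), 182 have WB-DWI/MRI, and the
#' per-assessor criterion indicators reproduce the published per-site counts
#' and the published confusion counts in both the 224-patient and the
#' 167-patient analysis cohorts.
#'
#' @return a \code{cohort} of 279 records.
#' @export
build_counts_fixture <- function() {
  # Strata of the 242 analyzable patients. Order (and patient ids) fixed:
  #   1-167   operable, MRI available   (48 reference-positive first)
  #   168-224 operable, no MRI          (14 reference-positive first)
  #   225-239 inoperable, MRI available
  #   240-242 inoperable, no MRI
  strata <- data.frame(
    stratum = c("om_pos", "om_neg", "ox_pos", "ox_neg", "im", "ix"),
    size = c(48, 119, 14, 43, 15, 3),
    stringsAsFactors = FALSE
  )
  idx <- split(seq_len(242), rep(strata$stratum, strata$size))
  # per-stratum per-modality positive counts, chosen so the confusion counts
  # of both analysis cohorts and the 242-wide site tallies all reconcile
  pos_n <- list(
    us = c(om_pos = 35, om_neg = 7, ox_pos = 5, ox_neg = 2, im = 6, ix = 0),
    ct = c(om_pos = 30, om_neg = 14, ox_pos = 8, ox_neg = 2, im = 4, ix = 0),
    mri = c(om_pos = 26, om_neg = 12, ox_pos = 0, ox_neg = 0, im = 6, ix = 0),
    surg = c(om_pos = 47, om_neg = 9, ox_pos = 12, ox_neg = 1, im = 9, ix = 0)
  )
  mri_avail <- rep(FALSE, 242)
  mri_avail[c(idx$om_pos, idx$om_neg, idx$im)] <- TRUE

  positives <- lapply(pos_n, function(p) {
    unlist(lapply(names(idx), function(s) idx[[s]][seq_len(p[[s]])]),
           use.names = FALSE)
  })

  site <- published_site_counts()
  crit <- list()
  for (key in names(ASSESSORS)) {
    m <- matrix(NA_integer_, 242, N_CRITERIA)
    assessed <- if (key == "mri") mri_avail else rep(TRUE, 242)
    m[assessed, ] <- 0L
    pos <- sort(positives[[key]])
    stopifnot(length(pos) == site[[key]]$any, all(assessed[pos]))
    m[pos, ] <- fill_criteria(length(pos), site[[key]]$counts, site[[key]]$n12)
    colnames(m) <- criterion_cols(key)
    crit[[key]] <- m
  }

  # Outcomes: reference-positive operable patients are R2 for tumor reasons
  # (23 suboptimal, 39 not feasible); reference-negatives split R0/R1 =
  # 145/17; the 18 inoperable are R2/inoperable.
  residual <- rep("R0", 242)
  reason <- rep("", 242)
  ref_pos <- c(idx$om_pos, idx$ox_pos)
  residual[ref_pos] <- "R2"
  reason[ref_pos] <- rep(c("suboptimal_after_max_effort", "not_feasible_at_laparoscopy"),
                         c(23, 39))
  inop <- c(idx$im, idx$ix)
  residual[inop] <- "R2"
  reason[inop] <- "inoperable"
  r1 <- idx$om_neg[seq_len(17)]
  residual[r1] <- "R1"

  # approach: not-feasible R2s were laparoscopies; 11 of the 18 inoperable
  # had diagnostic laparoscopy only; 5 R0s laparoscopic; 25 combined
  approach <- rep("laparotomy", 242)
  approach[reason == "not_feasible_at_laparoscopy"] <- "laparoscopy"
  approach[inop[seq_len(11)]] <- "laparoscopy"
  r0 <- which(residual == "R0")
  approach[r0[seq_len(5)]] <- "laparoscopy"
  approach[r0[6:30]] <- "combined"

  analyzable <- data.frame(
    patient_id = sprintf("F%04d", seq_len(242)),
    mri_available = as.integer(mri_avail),
    outcome_residual = residual,
    outcome_r2_reason = reason,
    approach = approach,
    excl_flags = "",
    stringsAsFactors = FALSE
  )
  analyzable <- cbind(analyzable, lapply(crit, as.data.frame))
  names(analyzable) <- sub("^(us|ct|mri|surg)\\.", "", names(analyzable))

  # 37 excluded recruits, flags cycling the seven codes (breakdown arbitrary)
  nx <- 37
  excluded <- data.frame(
    patient_id = sprintf("F%04d", 242 + seq_len(nx)),
    mri_available = 0L,
    outcome_residual = "R0",
    outcome_r2_reason = "",
    approach = "laparotomy",
    excl_flags = rep_len(exclusion_codes(), nx),
    stringsAsFactors = FALSE
  )
  for (col in unlist(lapply(names(ASSESSORS), criterion_cols))) {
    excluded[[col]] <- NA_integer_
  }
  df <- rbind(analyzable, excluded[names(analyzable)])
  new_cohort(df, provenance = "build_counts_fixture: 279 synthetic records reproducing published marginal counts")
}

#' Path of the packaged counts-fixture CSV
#'
#' @return file path of \code{study_counts_fixture.csv} inside the installed
#'   package.
#' @export
counts_fixture_path <- function() {
  system.file("extdata", "study_counts_fixture.csv", package = "resectability",
              mustWork = TRUE)
}
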
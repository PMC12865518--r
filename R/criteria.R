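# Patient-level resectability classification from the eight ESMO-ESGO
# site-involvement criteria, and derivation of the surgical-outcome reference.

#' Site vocabulary of the eight non-resectability criteria
#'
#' Fixed order: (1) small intestine, (2) small-bowel mesentery root,
#' (3) stomach/duodenum, (4) pancreas head/middle, (5) non-resectable liver
#' metastases, (6) hepatic hilum and celiac trunk, (7) non-resectable
#' abdominal lymph nodes, (8) non-resectable extra-abdominal metastasis.
#' Criterion 8 encodes only extra-abdominal disease judged non-resectable;
#' resectable extra-abdominal findings (e.g. isolated cardiophrenic nodes)
#' never set it.
#'
#' @return character vector of 8 site labels.
#' @export
criterion_sites <- function() {
  c("small_intestine", "small_bowel_mesentery", "stomach_duodenum",
    "pancreas", "liver", "hepatic_hilum_celiac_trunk",
    "abdominal_lymph_nodes", "extra_abdominal")
}

#' Classify a site assessment into a patient-level prediction
#'
#' The OR rule: a patient is predicted non-resectable if any of the eight
#' criteria is present, resectable if all eight are absent. If some criteria
#' are unassessed (NA) and none of the assessed ones is present, resectability
#' cannot be ruled out and the prediction is indeterminate.
#'
#' @param criteria integer vector of length 8 with values 0 (absent),
#'   1 (present) or NA (not assessed); or a matrix/data frame with 8 columns
#'   (one row per assessment).
#' @return character: \code{"resectable"}, \code{"non_resectable"} or
#'   \code{"indeterminate"}; a vector when given a matrix.
#' @export
classify_prediction <- function(criteria) {
  m <- if (is.matrix(criteria) || is.data.frame(criteria)) {
    as.matrix(criteria)
  } else {
    matrix(criteria, nrow = 1)
  }
  if (ncol(m) != N_CRITERIA) {
    stop("assessment must have exactly ", N_CRITERIA, " criterion slots", call. = FALSE)
  }
  any_present <- rowSums(m == 1, na.rm = TRUE) > 0
  all_absent <- rowSums(m == 0, na.rm = TRUE) == N_CRITERIA
  out <- rep("indeterminate", nrow(m))
  out[any_present] <- "non_resectable"
  out[all_absent] <- "resectable"
  out
}

#' Patient-level predictions of one assessor over a cohort
#'
#' @param cohort a \code{cohort}.
#' @param assessor one of \code{"us"}, \code{"ct"}, \code{"mri"},
#'   \code{"surg"} (long forms accepted).
#' @return character vector, one prediction per record; \code{NA} where the
#'   assessor did not examine the patient at all.
#' @export
predict_cohort <- function(cohort, assessor) {
  key <- assessor_key(assessor)
  crit <- as.matrix(cohort$data[, criterion_cols(key), drop = FALSE])
  out <- classify_prediction(crit)
  out[!has_assessment(cohort, key)] <- NA_character_
  out
}

#' Derive the reference-standard label from the surgical outcome
#'
#' R0 (no macroscopic residuum) and R1 (residuum <= 1 cm) are resectable;
#' R2 (residuum > 1 cm, or cytoreduction not attempted/feasible) is
#' non-resectable, except when the R2 outcome was due to inoperability
#' (patient frailty), which yields the sentinel \code{"excluded_inoperable"}.
#'
#' @param residual character vector of \code{"R0"}/\code{"R1"}/\code{"R2"}.
#' @param r2_reason character vector of R2 reasons
#'   (\code{"suboptimal_after_max_effort"}, \code{"not_feasible_at_laparoscopy"},
#'   \code{"inoperable"}); ignored for non-R2 outcomes.
#' @return character vector of reference labels.
#' @export
derive_reference <- function(residual, r2_reason = "") {
  residual <- as.character(residual)
  r2_reason <- rep_len(as.character(r2_reason), length(residual))
  if (!all(residual %in% RESIDUAL_LEVELS)) {
    stop("residual class must be R0, R1 or R2", call. = FALSE)
  }
  is_r2 <- residual == "R2"
  if (any(is_r2 & (is.na(r2_reason) | r2_reason == ""))) {
    stop("R2 outcome requires a reason", call. = FALSE)
  }
  if (!all(r2_reason[is_r2] %in% R2_REASONS)) {
    stop("unknown R2 reason", call. = FALSE)
  }
  out <- rep("resectable", length(residual))
  out[is_r2] <- "non_resectable"
  out[is_r2 & r2_reason == "inoperable"] <- "excluded_inoperable"
  out
}

#' Reference labels for a cohort
#' @param cohort a \code{cohort}.
#' @return character vector of reference labels, one per record.
#' @export
reference_cohort <- function(cohort) {
  derive_reference(cohort$data$outcome_residual, cohort$data$outcome_r2_reason)
}

#' Site-involvement frequency table for one assessor
#'
#' Counts, for each of the eight criteria plus the derived rows
#' "criterion 1 and/or 2" and "any of 1-8", how many assessed patients the
#' assessor scored as involved, with percentages of the assessor-assessed
#' records rounded half-up to 1 decimal.
#'
#' @param cohort a \code{cohort}.
#' @param assessor assessor label.
#' @return data frame with columns \code{site}, \code{count}, \code{n},
#'   \code{pct}.
#' @export
site_frequency_table <- function(cohort, assessor) {
  key <- assessor_key(assessor)
  assessed <- has_assessment(cohort, key)
  if (!any(assessed)) stop("assessor ", key, " absent from every record", call. = FALSE)
  crit <- as.matrix(cohort$data[assessed, criterion_cols(key), drop = FALSE])
  n <- nrow(crit)
  counts <- colSums(crit == 1, na.rm = TRUE)
  c12 <- sum(rowSums(crit[, 1:2, drop = FALSE] == 1, na.rm = TRUE) > 0)
  any8 <- sum(rowSums(crit == 1, na.rm = TRUE) > 0)
  data.frame(
    site = c(criterion_sites(), "criterion_1_and_or_2", "any_of_1_8"),
    count = as.integer(c(counts, c12, any8)),
    n = n,
    pct = round_half_up(100 * c(counts, c12, any8) / n, 1),
    row.names = NULL
  )
}
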
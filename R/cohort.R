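# Cohort data model: one row per patient, wide format, with assessor-prefixed
# ternary criterion columns. Canonical interchange format is CSV.

ASSESSORS <- c(us = "US", ct = "CT", mri = "WB_DWI_MRI", surg = "SURG_EXPL")
N_CRITERIA <- 8L

#' Exclusion-reason vocabulary
#'
#' The seven pre-specified reasons a recruited patient can be excluded from
#' analysis: mandatory index tests not performed, no reference standard
#' (no surgery and no usable follow-up), more than four weeks between imaging
#' and surgery, histology showing a non-primary or benign/borderline tumor,
#' death before the index tests, protocol non-compliance, and missing
#' index-test or surgery data.
#'
#' @return character vector of the seven exclusion codes.
#' @export
exclusion_codes <- function() {
  c("index_tests_not_performed",
    "no_reference_standard",
    "interval_over_4_weeks",
    "non_primary_or_benign_histology",
    "death_before_index_tests",
    "protocol_noncompliance",
    "missing_data")
}

criterion_cols <- function(assessor) {
  key <- assessor_key(assessor)
  paste0(key, "_c", seq_len(N_CRITERIA))
}

# Normalize an assessor label ("US", "us", "WB_DWI_MRI", "mri", ...) to the
# short column-prefix key.
assessor_key <- function(assessor) {
  a <- tolower(as.character(assessor))
  a[a == "wb_dwi_mri"] <- "mri"
  a[a == "surg_expl"] <- "surg"
  if (!all(a %in% names(ASSESSORS))) {
    stop("unknown assessor: ", paste(setdiff(a, names(ASSESSORS)), collapse = ", "),
         call. = FALSE)
  }
  a
}

cohort_schema_cols <- function() {
  c("patient_id", "mri_available", "outcome_residual", "outcome_r2_reason",
    "approach", "excl_flags",
    unlist(lapply(names(ASSESSORS), criterion_cols), use.names = FALSE))
}

#' Construct a cohort object
#'
#' A cohort wraps a wide per-patient data frame (one row per patient, ternary
#' 0/1/NA criterion columns per assessor) together with an append-only
#' provenance trail recording every subsetting step applied to it.
#'
#' @param data data frame with the canonical cohort columns.
#' @param provenance character vector of processing-history entries.
#' @return an object of class \code{cohort}.
#' @export
new_cohort <- function(data, provenance = "constructed") {
  stopifnot(is.data.frame(data))
  missing <- setdiff(cohort_schema_cols(), names(data))
  if (length(missing) > 0) {
    stop("cohort data missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(data$patient_id)) {
    stop("duplicate patient_id: ",
         paste(unique(data$patient_id[duplicated(data$patient_id)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(data = data, provenance = provenance), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$data), " patients\n", sep = "")
  cat("provenance:\n")
  for (p in x$provenance) cat("  - ", p, "\n", sep = "")
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort a \code{cohort} object.
#' @return integer row count.
#' @export
n_patients <- function(cohort) nrow(cohort$data)

RESIDUAL_LEVELS <- c("R0", "R1", "R2")
R2_REASONS <- c("suboptimal_after_max_effort", "not_feasible_at_laparoscopy",
                "inoperable")
APPROACHES <- c("laparoscopy", "laparotomy", "combined")

# Validate parsed cohort rows; returns a list of problem records
# (row, column, value, message), empty when clean.
validate_cohort_data <- function(df) {
  problems <- list()
  note <- function(row, column, value, message) {
    problems[[length(problems) + 1L]] <<-
      list(row = row, column = column, value = as.character(value),
           message = message)
  }
  dup <- unique(df$patient_id[duplicated(df$patient_id)])
  for (id in dup) {
    note(which(df$patient_id == id)[2], "patient_id", id, "duplicate patient_id")
  }
  check_enum <- function(column, allowed, allow_empty = TRUE) {
    vals <- as.character(df[[column]])
    ok <- vals %in% allowed | (allow_empty & (is.na(vals) | vals == ""))
    for (i in which(!ok)) note(i, column, vals[i], "unknown enum token")
  }
  check_enum("outcome_residual", RESIDUAL_LEVELS)
  check_enum("outcome_r2_reason", R2_REASONS)
  check_enum("approach", APPROACHES)
  mri <- as.character(df$mri_available)
  for (i in which(!mri %in% c("0", "1"))) {
    note(i, "mri_available", mri[i], "mri_available must be 0 or 1")
  }
  # r2_reason present iff outcome is R2
  res <- as.character(df$outcome_residual)
  reason <- as.character(df$outcome_r2_reason)
  has_reason <- !is.na(reason) & reason != ""
  for (i in which(res == "R2" & !has_reason)) {
    note(i, "outcome_r2_reason", "", "R2 outcome requires a reason")
  }
  for (i in which(res %in% c("R0", "R1") & has_reason)) {
    note(i, "outcome_r2_reason", reason[i], "reason given for non-R2 outcome")
  }
  flags <- strsplit(as.character(ifelse(is.na(df$excl_flags), "", df$excl_flags)),
                    ";", fixed = TRUE)
  for (i in seq_along(flags)) {
    bad <- setdiff(trimws(flags[[i]]), c(exclusion_codes(), ""))
    if (length(bad) > 0) note(i, "excl_flags", paste(bad, collapse = ";"),
                              "unknown exclusion code")
  }
  for (col in unlist(lapply(names(ASSESSORS), criterion_cols))) {
    vals <- as.character(df[[col]])
    ok <- is.na(vals) | vals %in% c("0", "1", "NA", "")
    for (i in which(!ok)) {
      note(i, col, vals[i], "criterion value must be 0, 1 or NA")
    }
  }
  problems
}

#' Read a cohort from CSV
#'
#' Parses the canonical wide per-patient CSV (see the package vignette for the
#' column schema). Criterion values are ternary and parsed strictly: only
#' \code{0}, \code{1} and \code{NA}/empty are accepted. A missing mandatory
#' column is a schema error; duplicate patient ids, unknown enum tokens and
#' malformed criterion cells are validation errors that name the offending row
#' and column.
#'
#' @param path path to a CSV file with the mandatory header.
#' @param schema_version schema identifier, currently \code{"1.0"}.
#' @param strict if \code{TRUE} (default) any validation problem aborts;
#'   otherwise offending rows are dropped and the collected problems are
#'   attached as attribute \code{"validation_report"}.
#' @return a \code{cohort}.
#' @export
read_cohort <- function(path, schema_version = "1.0", strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!identical(schema_version, "1.0")) {
    stop("unsupported schema_version: ", schema_version, call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = "character", na.strings = "NA")
  missing <- setdiff(cohort_schema_cols(), names(df))
  if (length(missing) > 0) {
    stop("schema error: missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  problems <- validate_cohort_data(df)
  if (length(problems) > 0) {
    if (strict) {
      p <- problems[[1]]
      stop(sprintf("validation error (%d problem(s)); first: row %d, column %s, value '%s': %s",
                   length(problems), p$row, p$column, p$value, p$message),
           call. = FALSE)
    }
    drop <- unique(vapply(problems, function(p) p$row, numeric(1)))
    message("read_cohort: dropping ", length(drop), " malformed row(s)")
    df <- df[-drop, , drop = FALSE]
  }
  df <- coerce_cohort_types(df)
  out <- new_cohort(df, provenance = paste0("read_cohort('", basename(path),
                                            "', schema 1.0): ", nrow(df), " records"))
  if (length(problems) > 0) attr(out, "validation_report") <- problems
  out
}

coerce_cohort_types <- function(df) {
  for (col in c("outcome_residual", "outcome_r2_reason", "approach", "excl_flags")) {
    v <- as.character(df[[col]])
    v[is.na(v)] <- ""
    df[[col]] <- v
  }
  df$mri_available <- as.integer(df$mri_available)
  for (col in unlist(lapply(names(ASSESSORS), criterion_cols))) {
    v <- as.character(df[[col]])
    v[v == ""] <- NA_character_
    df[[col]] <- as.integer(v)
  }
  df
}

#' Write a cohort to CSV
#'
#' Inverse of \code{\link{read_cohort}}: a write/read round trip reproduces
#' all field values exactly.
#'
#' @param cohort a \code{cohort}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort$data, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Write a validation report as JSON lines
#'
#' @param problems list of problem records as attached by
#'   \code{\link{read_cohort}} (attribute \code{"validation_report"}).
#' @param path output path; one JSON object per line.
#' @return the path, invisibly.
#' @export
write_validation_report <- function(problems, path) {
  lines <- vapply(problems, function(p) {
    jsonlite::toJSON(p, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Apply the eligibility rules
#'
#' Removes every record carrying at least one exclusion flag and reports the
#' per-code exclusion counts, mirroring the recruitment flowchart of the study
#' design (recruited minus excluded = analyzed).
#'
#' @param cohort a \code{cohort} whose \code{excl_flags} field is populated
#'   (empty string = eligible).
#' @return list with elements \code{cohort} (eligible records) and
#'   \code{exclusion_report} (named integer vector of counts per code, plus
#'   \code{n_excluded}).
#' @export
apply_eligibility <- function(cohort) {
  flags <- strsplit(as.character(ifelse(cohort$data$excl_flags == "", NA_character_,
                                        cohort$data$excl_flags)), ";", fixed = TRUE)
  excluded <- !vapply(flags, function(f) all(is.na(f)), logical(1))
  codes <- unlist(flags[excluded], use.names = FALSE)
  report <- table(factor(trimws(codes), levels = exclusion_codes()))
  kept <- cohort$data[!excluded, , drop = FALSE]
  out <- new_cohort(kept, provenance = c(cohort$provenance,
    sprintf("apply_eligibility: %d excluded, %d retained", sum(excluded), nrow(kept))))
  list(cohort = out,
       exclusion_report = c(as.list(report), n_excluded = sum(excluded)))
}

#' Exclude inoperable patients
#'
#' Drops patients whose suboptimal outcome was due to inoperability (frailty:
#' the patient could not tolerate the surgery needed), not tumor
#' non-resectability. These patients carry no information about the
#' discrimination task and are removed before accuracy analyses.
#'
#' @param cohort a \code{cohort} with outcomes populated.
#' @return the filtered \code{cohort}.
#' @export
exclude_inoperable <- function(cohort) {
  drop <- cohort$data$outcome_residual == "R2" &
    cohort$data$outcome_r2_reason == "inoperable"
  kept <- cohort$data[!drop, , drop = FALSE]
  new_cohort(kept, provenance = c(cohort$provenance,
    sprintf("exclude_inoperable: %d removed, %d retained", sum(drop), nrow(kept))))
}

# TRUE where the record carries an assessment from `assessor`: MRI requires
# the availability flag; any assessor additionally requires at least one
# non-missing criterion cell.
has_assessment <- function(cohort, assessor) {
  key <- assessor_key(assessor)
  crit <- as.matrix(cohort$data[, criterion_cols(key), drop = FALSE])
  present <- rowSums(!is.na(crit)) > 0
  if (key == "mri") present <- present & cohort$data$mri_available == 1L
  present
}

#' Complete-case subset by required assessors
#'
#' Retains the records that carry an assessment from every required assessor
#' (e.g. the three-imaging-modality subcohort requires ultrasound, CT and
#' WB-DWI/MRI).
#'
#' @param cohort a \code{cohort}.
#' @param required_assessors character vector of assessors, e.g.
#'   \code{c("us", "ct", "mri")}; long forms (\code{"WB_DWI_MRI"}) accepted.
#' @return the filtered \code{cohort}.
#' @export
complete_case_subset <- function(cohort, required_assessors) {
  keys <- assessor_key(required_assessors)
  keep <- rep(TRUE, nrow(cohort$data))
  for (k in keys) keep <- keep & has_assessment(cohort, k)
  kept <- cohort$data[keep, , drop = FALSE]
  new_cohort(kept, provenance = c(cohort$provenance,
    sprintf("complete_case_subset({%s}): %d retained",
            paste(keys, collapse = ","), nrow(kept))))
}
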
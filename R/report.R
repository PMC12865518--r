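# End-to-end analysis pipeline: reads a cohort, applies the eligibility and
# subcohort rules, and writes frequency, performance, agreement and
# non-inferiority outputs plus a reproducibility manifest.

#' Analysis configuration
#'
#' @param input path to a cohort CSV.
#' @param require_mri build the complete-case subcohort requiring all three
#'   imaging modalities (default TRUE).
#' @param exclude_inoperable drop inoperable patients before accuracy
#'   analyses (default TRUE).
#' @param margin non-inferiority margin, default 0.05.
#' @param alpha one-sided significance level, default 0.05.
#' @param proportion_method,auc_method interval methods (see
#'   \code{\link{point_metrics}}).
#' @param agreement_convention see \code{\link{agreement_metrics}}.
#' @param betas F-score weights, default \code{c(1, 0.5)}.
#' @param outdir output directory (created if absent).
#' @param seed seed for the bootstrap variance engine.
#' @return list of class \code{analysis_config}.
#' @export
analysis_config <- function(input, require_mri = TRUE, exclude_inoperable = TRUE,
                            margin = 0.05, alpha = 0.05,
                            proportion_method = "wilson",
                            auc_method = "delong_binary",
                            agreement_convention = "reference_conditioned",
                            betas = c(1, 0.5), outdir = tempfile("analysis_"),
                            seed = 1) {
  structure(list(input = input, require_mri = require_mri,
                 exclude_inoperable = exclude_inoperable, margin = margin,
                 alpha = alpha, proportion_method = proportion_method,
                 auc_method = auc_method,
                 agreement_convention = agreement_convention, betas = betas,
                 outdir = outdir, seed = seed),
            class = "analysis_config")
}

md_table <- function(df) {
  fmt <- function(v) ifelse(is.na(v), "NA",
                            ifelse(is.numeric(v), formatC(v, format = "g", digits = 6),
                                   as.character(v)))
  cells <- vapply(df, function(col) as.character(fmt(col)), character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}

#' Run the full analysis pipeline
#'
#' Produces, under \code{config$outdir}: per-assessor site-frequency tables,
#' study-style performance tables for the full analysis cohort and (when
#' \code{require_mri}) the complete-case subcohort, per-site agreement tables
#' for each imaging modality, paired non-inferiority results (ultrasound vs
#' CT and, when available, ultrasound vs WB-DWI/MRI; AUC and F1 statistics),
#' and a JSON manifest with the fully resolved configuration, package
#' version, seed and row-drop log. Identical inputs and configuration yield
#' an identical bundle. All rendered numbers come from the package's single
#' rounding policy.
#'
#' @param config an \code{\link{analysis_config}}.
#' @return invisibly, a list with every computed object.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log <<- c(log, msg)
  }

  cohort <- read_cohort(config$input)
  elig <- apply_eligibility(cohort)
  say("eligibility: %d recruited, %d excluded, %d analyzable",
      n_patients(cohort), elig$exclusion_report$n_excluded, n_patients(elig$cohort))
  analysis_pop <- elig$cohort
  if (n_patients(analysis_pop) == 0) stop("empty cohort after eligibility", call. = FALSE)

  # (1) site-frequency tables over the analyzable population
  freq <- list()
  for (key in names(ASSESSORS)) {
    freq[[key]] <- tryCatch(site_frequency_table(analysis_pop, key),
                            error = function(e) NULL)
    if (!is.null(freq[[key]])) {
      utils::write.csv(freq[[key]],
                       file.path(config$outdir, paste0("site_frequency_", key, ".csv")),
                       row.names = FALSE)
    }
  }

  # (2) accuracy cohorts
  full <- if (config$exclude_inoperable) exclude_inoperable(analysis_pop) else analysis_pop
  say("accuracy cohort: %d patients", n_patients(full))
  cohorts <- list(full_cohort = full)
  if (config$require_mri) {
    sub <- complete_case_subset(full, c("us", "ct", "mri"))
    say("complete-case subcohort: %d patients", n_patients(sub))
    cohorts$complete_case <- sub
  }
  metric_tables <- list()
  for (label in names(cohorts)) {
    co <- cohorts[[label]]
    assessors <- c("us", "ct", if (label == "complete_case") "mri", "surg")
    counts <- lapply(stats::setNames(assessors, assessors), function(a) {
      confusion_cohort(co, a)
    })
    tab <- render_metric_table(counts, betas = config$betas,
                               proportion_method = config$proportion_method,
                               auc_method = config$auc_method)
    metric_tables[[label]] <- list(counts = counts, table = tab)
    utils::write.csv(tab, file.path(config$outdir, paste0("performance_", label, ".csv")),
                     row.names = FALSE)
    writeLines(md_table(tab),
               file.path(config$outdir, paste0("performance_", label, ".md")))
  }

  # (3) agreement of each imaging modality against surgical exploration
  agreement <- list()
  for (key in c("us", "ct", "mri")) {
    agreement[[key]] <- tryCatch(
      agreement_report(analysis_pop, key, config$agreement_convention),
      error = function(e) NULL)
    if (!is.null(agreement[[key]])) {
      utils::write.csv(agreement[[key]],
                       file.path(config$outdir, paste0("agreement_", key, ".csv")),
                       row.names = FALSE)
    }
  }

  # (4) paired non-inferiority on the complete-case (or full) cohort
  noninf_cohort <- cohorts[[length(cohorts)]]
  comparisons <- list(c("us", "ct"))
  if (config$require_mri) comparisons <- c(comparisons, list(c("us", "mri")))
  noninf <- list()
  for (cmp in comparisons) {
    label <- paste(cmp, collapse = "_vs_")
    pairs <- paired_from_cohort(noninf_cohort, cmp[1], cmp[2])
    res <- list(
      auc = paired_auc_noninf(pairs, config$margin, config$alpha),
      f1 = paired_f1_noninf(pairs, config$margin, config$alpha,
                            engine = "bootstrap", seed = config$seed)
    )
    noninf[[label]] <- res
    for (stat in names(res)) {
      r <- res[[stat]]
      say("%s [%s]: delta=%+.3f SE=%.4f p=%.2g -> %s", label,
          r$statistic_name, r$delta_hat, r$SE_diff, r$p_one_sided, r$conclusion)
    }
    jsonlite::write_json(
      lapply(res, function(r) r[!vapply(r, is.null, logical(1))]),
      file.path(config$outdir, paste0("noninferiority_", label, ".json")),
      auto_unbox = TRUE, digits = NA)
  }

  # (5) manifest
  manifest <- list(
    config = unclass(config),
    package_version = as.character(utils::packageVersion("resectability")),
    exclusion_report = elig$exclusion_report,
    provenance = noninf_cohort$provenance,
    log = log
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohorts = cohorts, frequency = freq,
                 metric_tables = metric_tables, agreement = agreement,
                 noninferiority = noninf, manifest = manifest))
}
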
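# Site-level agreement between an imaging modality and surgical exploration:
# 2x2 cross-tabulation and overall/positive/negative percent agreement.

#' Construct an agreement table
#'
#' @param a both assessors positive.
#' @param b reference positive, imaging negative.
#' @param c imaging positive, reference negative.
#' @param d both negative.
#' @param reference label of the reference assessor (default surgical
#'   exploration).
#' @return object of class \code{agreement_table}.
#' @export
agreement_table <- function(a, b, c, d, reference = "surg") {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  counts <- as.integer(counts)
  structure(list(a = counts[1], b = counts[2], c = counts[3], d = counts[4],
                 reference = reference),
            class = "agreement_table")
}

#' @export
print.agreement_table <- function(x, ...) {
  cat(sprintf("<agreement_table> a=%d b=%d c=%d d=%d (n=%d, ref=%s)\n",
              x$a, x$b, x$c, x$d, x$a + x$b + x$c + x$d, x$reference))
  invisible(x)
}

#' Cross-tabulate one imaging modality against surgical exploration at a site
#'
#' Builds the 2x2 table of imaging vs surgical exploration for one criterion
#' (or for the patient-level "any criterion" OR label). Records lacking either
#' assessment, or with NA at the criterion for either assessor, are dropped
#' with a message giving the count.
#'
#' @param cohort a \code{cohort}.
#' @param imaging imaging assessor (\code{"us"}, \code{"ct"}, \code{"mri"}).
#' @param criterion integer 1..8, or \code{"any"} for the patient-level OR
#'   label.
#' @return an \code{agreement_table} with surgical exploration as reference.
#' @export
crosstab_site <- function(cohort, imaging, criterion = "any") {
  key <- assessor_key(imaging)
  if (key == "surg") stop("imaging assessor expected, not the reference", call. = FALSE)
  if (identical(criterion, "any")) {
    img <- predict_cohort(cohort, key)
    ref <- predict_cohort(cohort, "surg")
    img_pos <- img == "non_resectable"
    ref_pos <- ref == "non_resectable"
    usable <- !is.na(img) & !is.na(ref) &
      img != "indeterminate" & ref != "indeterminate"
  } else {
    stopifnot(criterion %in% seq_len(N_CRITERIA))
    img_v <- cohort$data[[paste0(key, "_c", criterion)]]
    ref_v <- cohort$data[[paste0("surg_c", criterion)]]
    img_pos <- img_v == 1L
    ref_pos <- ref_v == 1L
    usable <- !is.na(img_v) & !is.na(ref_v)
  }
  if (!any(usable)) stop("no records with both assessments", call. = FALSE)
  if (any(!usable)) {
    message(sprintf("crosstab_site(%s, %s): dropping %d record(s) without both assessments",
                    key, as.character(criterion), sum(!usable)))
  }
  img_pos <- img_pos[usable]
  ref_pos <- ref_pos[usable]
  agreement_table(a = sum(img_pos & ref_pos), b = sum(!img_pos & ref_pos),
                  c = sum(img_pos & !ref_pos), d = sum(!img_pos & !ref_pos))
}

#' Overall, positive and negative percent agreement
#'
#' Under the \code{"reference_conditioned"} convention, PPA and NPA condition
#' on the reference assessor: OPA = (a+d)/n, PPA = a/(a+b), NPA = d/(c+d).
#' Under \code{"specific_agreement"}: PPA = 2a/(2a+b+c), NPA = 2d/(2d+b+c)
#' (OPA is identical under both). Zero-denominator metrics are \code{NA}.
#'
#' @param table an \code{agreement_table}.
#' @param convention \code{"reference_conditioned"} (default) or
#'   \code{"specific_agreement"}.
#' @return list with \code{opa}, \code{ppa}, \code{npa} (proportions) and
#'   \code{convention}.
#' @export
agreement_metrics <- function(table,
                              convention = c("reference_conditioned",
                                             "specific_agreement")) {
  convention <- match.arg(convention)
  a <- table$a; b <- table$b; cc <- table$c; d <- table$d
  n <- a + b + cc + d
  if (n == 0) stop("empty agreement table", call. = FALSE)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  if (convention == "reference_conditioned") {
    list(opa = (a + d) / n, ppa = safe(a, a + b), npa = safe(d, cc + d),
         convention = convention)
  } else {
    list(opa = (a + d) / n, ppa = safe(2 * a, 2 * a + b + cc),
         npa = safe(2 * d, 2 * d + b + cc), convention = convention)
  }
}

#' Reconstruct the joint 2x2 table from printed margins and overall agreement
#'
#' Study reports often print only the two positive margins and the overall
#' percent agreement of a 2x2 cross-classification. Given n, the reference
#' positives (a+b), the imaging positives (a+c) and OPA, the concordant-pair
#' count is n - round(OPA * n) discordant cells, so
#' a = (ref_pos + img_pos - (n - round(opa * n))) / 2. The table is returned
#' when that value is a non-negative integer consistent with all margins;
#' otherwise an error is raised.
#'
#' @param n total patients.
#' @param ref_pos reference-positive margin (a+b).
#' @param img_pos imaging-positive margin (a+c).
#' @param opa overall percent agreement as a proportion.
#' @return an \code{agreement_table}.
#' @export
reconstruct_joint_from_margins <- function(n, ref_pos, img_pos, opa) {
  stopifnot(n > 0, ref_pos >= 0, img_pos >= 0, ref_pos <= n, img_pos <= n,
            opa >= 0, opa <= 1)
  discordant <- n - round(opa * n)
  a2 <- ref_pos + img_pos - discordant
  if (a2 %% 2 != 0) stop("no consistent integer table (parity)", call. = FALSE)
  a <- a2 / 2
  b <- ref_pos - a
  cc <- img_pos - a
  d <- n - a - b - cc
  if (a < 0 || b < 0 || cc < 0 || d < 0) {
    stop("no consistent integer table (negative cell)", call. = FALSE)
  }
  agreement_table(a = a, b = b, c = cc, d = d)
}

#' Long-format agreement report over all sites
#'
#' Runs \code{\link{crosstab_site}} and \code{\link{agreement_metrics}} for
#' criteria 1..8 and the patient-level "any" label, for one imaging modality.
#'
#' @param cohort a \code{cohort}.
#' @param imaging imaging assessor.
#' @param convention agreement convention (see
#'   \code{\link{agreement_metrics}}).
#' @return data frame with columns \code{site}, \code{a}, \code{b}, \code{c},
#'   \code{d}, \code{opa}, \code{ppa}, \code{npa}, \code{convention}.
#' @export
agreement_report <- function(cohort, imaging,
                             convention = "reference_conditioned") {
  sites <- c(as.list(seq_len(N_CRITERIA)), list("any"))
  labels <- c(criterion_sites(), "any_of_1_8")
  rows <- lapply(seq_along(sites), function(i) {
    tab <- crosstab_site(cohort, imaging, sites[[i]])
    m <- agreement_metrics(tab, convention)
    data.frame(site = labels[i], a = tab$a, b = tab$b, c = tab$c, d = tab$d,
               opa = m$opa, ppa = m$ppa, npa = m$npa,
               convention = m$convention, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
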
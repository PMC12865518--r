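test_that("CSV round trip preserves every field exactly", {
  fx <- build_counts_fixture()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cohort(fx, tmp)
  back <- read_cohort(tmp)
  expect_identical(fx$data, back$data)
  expect_equal(n_patients(back), 279)
})

test_that("reader enforces schema and ternary criterion domain", {
  df <- make_cohort_df(3)
  tmp <- withr::local_tempfile(fileext = ".csv")

  # empty file with valid header -> 0 records
  utils::write.csv(df[0, ], tmp, row.names = FALSE, quote = FALSE)
  expect_equal(n_patients(read_cohort(tmp)), 0)

  # missing mandatory column -> schema error
  utils::write.csv(df[, -2], tmp, row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(tmp), "schema error.*mri_available")

  # criterion token outside {0,1,NA} -> validation error naming the cell
  bad <- df
  bad$us_c3[2] <- 2L
  utils::write.csv(bad, tmp, row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(tmp), "row 2, column us_c3")

  # duplicate patient id -> validation error
  dup <- df
  dup$patient_id[2] <- dup$patient_id[1]
  utils::write.csv(dup, tmp, row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(tmp), "duplicate patient_id")

  # unknown enum token -> validation error naming row and column
  bad2 <- df
  bad2$outcome_residual[3] <- "R9"
  utils::write.csv(bad2, tmp, row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(tmp), "row 3, column outcome_residual")

  # non-strict mode drops malformed rows and attaches the report
  expect_message(out <- read_cohort(tmp, strict = FALSE), "dropping 1")
  expect_equal(n_patients(out), 2)
  report <- attr(out, "validation_report")
  expect_length(report, 1)
  tmp2 <- withr::local_tempfile(fileext = ".jsonl")
  write_validation_report(report, tmp2)
  parsed <- jsonlite::fromJSON(readLines(tmp2)[1])
  expect_equal(parsed$column, "outcome_residual")
})

test_that("eligibility filtering reproduces the recruitment flow", {
  fx <- build_counts_fixture()
  res <- apply_eligibility(fx)
  expect_equal(n_patients(res$cohort), 242)
  expect_equal(res$exclusion_report$n_excluded, 37)
  expect_equal(sum(unlist(res$exclusion_report[exclusion_codes()])), 37)

  # no flags -> identity with empty report
  clean <- new_cohort(make_cohort_df(5))
  res2 <- apply_eligibility(clean)
  expect_equal(n_patients(res2$cohort), 5)
  expect_equal(res2$exclusion_report$n_excluded, 0)

  # all flagged -> empty cohort, totals = input size
  flagged <- make_cohort_df(4)
  flagged$excl_flags <- exclusion_codes()[1:4]
  res3 <- apply_eligibility(new_cohort(flagged))
  expect_equal(n_patients(res3$cohort), 0)
  expect_equal(res3$exclusion_report$n_excluded, 4)
})

test_that("inoperable exclusion and complete-case subsetting reproduce cohort sizes", {
  c242 <- fixture_242()
  c224 <- exclude_inoperable(c242)
  expect_equal(n_patients(c224), 224)
  c167 <- complete_case_subset(c224, c("us", "ct", "mri"))
  expect_equal(n_patients(c167), 167)

  # no R2 records -> identity
  plain <- new_cohort(make_cohort_df(6))
  expect_equal(n_patients(exclude_inoperable(plain)), 6)

  # only inoperable records -> empty
  inop <- make_cohort_df(3)
  inop$outcome_residual <- "R2"
  inop$outcome_r2_reason <- "inoperable"
  expect_equal(n_patients(exclude_inoperable(new_cohort(inop))), 0)

  # required set all assessed -> identity; impossible set -> empty
  expect_equal(n_patients(complete_case_subset(c242, "us")), 242)
  nomri <- make_cohort_df(4, mri_available = 0L)
  expect_equal(n_patients(complete_case_subset(new_cohort(nomri), c("us", "mri"))), 0)
})

test_that("subsetting operations commute", {
  c242 <- fixture_242()
  ab <- complete_case_subset(exclude_inoperable(c242), c("us", "ct", "mri"))
  ba <- exclude_inoperable(complete_case_subset(c242, c("us", "ct", "mri")))
  expect_identical(ab$data, ba$data)
})

test_that("reference-positive count is consistent across assessors within a cohort", {
  c242 <- fixture_242()
  c224 <- exclude_inoperable(c242)
  c167 <- complete_case_subset(c224, c("us", "ct", "mri"))
  pos224 <- vapply(c("us", "ct", "surg"), function(a) {
    cc <- suppressMessages(confusion_cohort(c224, a))
    cc$tp + cc$fn
  }, numeric(1))
  pos167 <- vapply(c("us", "ct", "mri", "surg"), function(a) {
    cc <- suppressMessages(confusion_cohort(c167, a))
    cc$tp + cc$fn
  }, numeric(1))
  expect_true(all(pos224 == 62))
  expect_true(all(pos167 == 48))
})
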
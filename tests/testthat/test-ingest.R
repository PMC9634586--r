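test_that("valid rows are retained and invalid rows excluded with reasons", {
  rec <- make_records(visit = c("2018-03-01", "2018-04-01", "2018-05-01",
                                "2018-06-01", "2018-07-01"),
                      drug = "diazepam", dose = 5, days = 10,
                      patient = c("P1", "P2", "P3", "P4", "P5"))
  path <- tempfile(fileext = ".csv")
  write_cohort(rec, path)
  cc <- read_prescriptions(path, default_registry)
  expect_equal(nrow(cc$records), 5L)
  expect_equal(cc$excluded_count, 0L)
  expect_equal(cc$study_year, 2018L)

  bad <- rec
  bad$drug_id[1] <- "phenobarbital"
  bad$days_supplied[2] <- 0L
  bad$daily_dose_mg[3] <- -2
  bad$visit_date[4] <- "not-a-date"
  write_cohort(bad, path)
  cc2 <- read_prescriptions(path, default_registry)
  expect_equal(nrow(cc2$records), 1L)
  expect_equal(cc2$excluded_count, 4L)
  expect_equal(cc2$exclusion_reasons[["unknown_drug"]], 1L)
  expect_equal(cc2$exclusion_reasons[["nonpositive_duration"]], 1L)
  expect_equal(cc2$exclusion_reasons[["nonpositive_dose"]], 1L)
  expect_equal(cc2$exclusion_reasons[["bad_date"]], 1L)
  # retained + excluded = input rows
  expect_equal(nrow(cc2$records) + cc2$excluded_count, nrow(bad))
})

test_that("a missing required column is a schema error naming it", {
  rec <- make_records("2018-03-01", "diazepam", 5, 10)
  rec$doctor_id <- NULL
  path <- tempfile(fileext = ".csv")
  write.csv(rec, path, row.names = FALSE)
  expect_error(read_prescriptions(path, default_registry), "doctor_id")
})

test_that("year truncation shortens supplies overrunning Dec 31", {
  rec <- make_records(c("2018-12-20", "2018-06-01", "2018-12-31"),
                      "diazepam", 5, 30)
  out <- truncate_to_year(rec, 2018L)
  expect_equal(out$days_supplied, c(12L, 30L, 1L))
  # idempotent
  expect_identical(truncate_to_year(out, 2018L)$days_supplied,
                   out$days_supplied)
})

test_that("write/read round-trip preserves every field", {
  rec <- generate_cohort(cohort_config(n_patients = 80, seed = 11))
  path <- tempfile(fileext = ".csv")
  write_cohort(rec, path)
  cc <- read_prescriptions(path, default_registry)
  # generated records are all valid; truncation only affects year overruns
  expect_equal(nrow(cc$records), nrow(rec))
  expect_equal(cc$excluded_count, 0L)
  back <- cc$records
  back <- back[order(back$patient_id, back$visit_date, back$drug_id), ]
  orig <- truncate_to_year(rec, 2018L)
  orig$visit_date <- as.Date(orig$visit_date)
  orig$gender[orig$gender == ""] <- NA_character_
  orig$diagnoses[is.na(orig$diagnoses)] <- ""
  orig <- orig[order(orig$patient_id, orig$visit_date, orig$drug_id), ]
  for (col in c("patient_id", "hospital_id", "doctor_id", "drug_id",
                "days_supplied", "gender", "age_years")) {
    expect_equal(back[[col]], orig[[col]], info = col)
  }
  expect_equal(back$visit_date, orig$visit_date)
  expect_equal(back$daily_dose_mg, orig$daily_dose_mg)
})

test_that("missing demographics soft-exclude patients without dropping records", {
  rec <- make_records(c("2018-02-01", "2018-03-01"), "diazepam", 5, 10,
                      patient = c("P1", "P2"))
  rec$gender[2] <- ""
  path <- tempfile(fileext = ".csv")
  write_cohort(rec, path)
  cc <- read_prescriptions(path, default_registry)
  expect_equal(nrow(cc$records), 2L)          # both retained descriptively
  expect_equal(cc$soft_excluded_patients, "P2")
  expect_equal(cc$records$complete_covariates, c(TRUE, FALSE))
})

test_that("an empty file yields an empty cohort with a warning", {
  path <- tempfile(fileext = ".csv")
  writeLines(paste(prescription_columns, collapse = ","), path)
  expect_warning(cc <- read_prescriptions(path, default_registry), "empty")
  expect_equal(nrow(cc$records), 0L)
  expect_equal(cc$excluded_count, 0L)
})
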
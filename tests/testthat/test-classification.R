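reg <- default_registry

test_that("overdose threshold is strict and long-term threshold inclusive", {
  expect_false(flag_overdose(40.0))
  expect_true(flag_overdose(40.01))
  expect_false(flag_overdose(0))
  expect_true(flag_long_term(90L))
  expect_false(flag_long_term(89L))
  expect_true(flag_long_term(365L))
})

test_that("hazardous is the conjunction of overdose and long-term", {
  m <- data.frame(patient_id = c("a", "b", "c", "d"),
                  max_window_avg_dme = c(50, 50, 10, 10),
                  max_continuous_days = c(100L, 30L, 100L, 30L))
  lab <- flag_hazardous(m)
  expect_equal(lab$hazardous, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(lab$hazardous, lab$overdose & lab$long_term)
  th <- attr(lab, "thresholds")
  expect_equal(th$dme_threshold, 40)
  expect_equal(th$day_threshold, 90L)
})

test_that("over-indication is a patient-level none-matches rule with prefix matching", {
  # no prefix of F32.1 is among clonazepam's epilepsy indications
  r1 <- make_records("2018-02-01", "clonazepam", 0.5, 10,
                     diagnoses = "F32.1")
  expect_true(flag_over_indication(r1, reg)$over_indication)

  # direct indication match
  r2 <- make_records("2018-02-01", "clonazepam", 0.5, 10,
                     diagnoses = "G40.3")
  expect_false(flag_over_indication(r2, reg)$over_indication)

  # one justified drug clears the patient under the none-matches rule
  r3 <- rbind(
    make_records("2018-02-01", "clonazepam", 0.5, 10, diagnoses = "G47.0"),
    make_records("2018-04-01", "zolpidem", 10, 10, diagnoses = "G47.0"))
  expect_false(flag_over_indication(r3, reg)$over_indication)
  pd <- flag_over_indication_by_drug(r3, reg)
  expect_true(pd$drug_over_indication[pd$drug_id == "clonazepam"])
  expect_false(pd$drug_over_indication[pd$drug_id == "zolpidem"])

  # no usable diagnosis data: NA
  r4 <- make_records("2018-02-01", "diazepam", 5, 10, diagnoses = "")
  expect_true(is.na(flag_over_indication(r4, reg)$over_indication))
})

test_that("diagnoses pool across the year's visits", {
  r <- rbind(
    make_records("2018-02-01", "clonazepam", 0.5, 10, diagnoses = "F32.1"),
    make_records("2018-09-01", "clonazepam", 0.5, 10, diagnoses = "G40.1"))
  # the September epilepsy diagnosis justifies the February dispensing too
  expect_false(flag_over_indication(r, reg)$over_indication)
})

test_that("classification partitions the cohort and is monotone in thresholds", {
  rec <- generate_cohort(cohort_config(n_patients = 400, seed = 17))
  cc <- clean_cohort(rec, reg)
  metrics <- compute_exposure(cc, reg)
  lab <- flag_hazardous(metrics)
  expect_equal(nrow(lab), nrow(metrics))
  expect_equal(sum(lab$hazardous) + sum(!lab$hazardous), nrow(metrics))

  grid_dme <- c(20, 40, 80)
  grid_day <- c(60L, 90L, 180L)
  counts <- sapply(grid_dme, function(dt)
    sapply(grid_day, function(dd)
      sum(flag_hazardous(metrics, dt, dd)$hazardous)))
  # nonincreasing along both threshold axes
  expect_true(all(apply(counts, 1, diff) <= 0))
  expect_true(all(apply(counts, 2, diff) <= 0))
})

test_that("planted archetypes get the labels they were built for", {
  haz <- generate_cohort(cohort_config(n_patients = 120, seed = 23,
                                       archetype_mix = c(hazardous = 1),
                                       missing_prob = 0))
  cas <- generate_cohort(cohort_config(n_patients = 120, seed = 29,
                                       archetype_mix = c(casual = 1),
                                       missing_prob = 0))
  lab_h <- classify_cohort(clean_cohort(haz, reg), registry = reg)
  lab_c <- classify_cohort(clean_cohort(cas, reg), registry = reg)
  expect_gte(mean(lab_h$hazardous), 0.9)
  expect_equal(sum(lab_c$hazardous), 0L)
})

test_that("an unmapped drug is a configuration error naming it", {
  r <- make_records("2018-02-01", "diazepam", 5, 10)
  reg2 <- reg
  reg2$indications$diazepam <- NULL
  expect_error(flag_over_indication(r, reg2), "diazepam")
})
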
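reg <- default_registry

test_that("drug-class usage categories follow the dispensed class set", {
  r <- rbind(make_records("2018-01-05", "clonazepam", 0.5, 10, patient = "P1"),
             make_records("2018-01-05", "zolpidem", 10, 10, patient = "P2"),
             make_records("2018-02-05", "zopiclone", 7.5, 10, patient = "P2"),
             make_records("2018-01-05", "diazepam", 5, 10, patient = "P3"),
             make_records("2018-03-05", "zolpidem", 10, 10, patient = "P3"))
  du <- classify_drug_use(r, reg)
  expect_equal(as.character(du$drug_use[du$patient_id == "P1"]), "BZD_only")
  expect_equal(as.character(du$drug_use[du$patient_id == "P2"]), "Z_only")
  expect_equal(as.character(du$drug_use[du$patient_id == "P3"]), "both")
})

test_that("DDD consumption follows its definition and is linear", {
  ddd_dz <- reg$drugs["diazepam", "ddd_mg"]
  r <- make_records("2018-01-05", "diazepam", ddd_dz, 10)
  tab <- ddd_consumption(r, reg)
  expect_equal(tab$ddd, 10)
  r2 <- r; r2$daily_dose_mg <- 2 * r2$daily_dose_mg
  expect_equal(ddd_consumption(r2, reg)$ddd, 2 * tab$ddd)
  empty <- ddd_consumption(r[0, ], reg)
  expect_equal(nrow(empty), 0L)
})

test_that("group comparisons pick the classical test for the data type", {
  # identical distributions duplicated: rank-sum statistic at its null centre
  x <- c(rnorm(30), rnorm(30))
  g <- rep(c("a", "b"), each = 30)
  x[31:60] <- x[1:30]
  gt <- compare_groups(x, g)
  expect_equal(gt$test_name, "wilcoxon_rank")
  expect_equal(gt$statistic, 30 * 30 / 2)

  # balanced 2x2 table: chi-square statistic 0
  resp <- rep(c("yes", "no", "yes", "no"), each = 10)
  grp <- rep(c("a", "a", "b", "b"), each = 10)
  gt2 <- compare_groups(resp, grp)
  expect_equal(gt2$test_name, "chi_square")
  expect_equal(gt2$statistic, 0)

  gt3 <- compare_groups(rnorm(90), rep(c("a", "b", "c"), 30))
  expect_equal(gt3$test_name, "kruskal_wallis")
  expect_true(gt3$p_value >= 0 && gt3$p_value <= 1)

  expect_error(compare_groups(rnorm(10), rep("a", 10)), "2 nonempty")
})

test_that("a single-patient cohort yields degenerate medians", {
  r <- make_records("2018-03-01", "clonazepam", 0.5, 10)
  cc <- clean_cohort(r, reg)
  m <- compute_exposure(cc, reg)
  lab <- classify_cohort(cc, m, reg)
  rep1 <- summarize_cohort(cc, m, lab, reg)
  s <- rep1$metric_summary
  expect_equal(unname(s["total_dme", ]), rep(100, 3))
  expect_equal(unname(s["max_continuous_days", "median"]), 10)
  expect_true(all(s[, "q1"] <= s[, "median"] & s[, "median"] <= s[, "q3"]))
})

test_that("report proportions are coherent", {
  rec <- generate_cohort(cohort_config(n_patients = 500, seed = 41))
  cc <- clean_cohort(rec, reg)
  m <- compute_exposure(cc, reg)
  lab <- classify_cohort(cc, m, reg)
  rep1 <- summarize_cohort(cc, m, lab, reg, n_total_outpatients = 2000)
  expect_equal(sum(rep1$drug_class_use_pct), 100, tolerance = 1e-9)
  expect_equal(rep1$n_bzra_patients, nrow(m))
  expect_equal(rep1$bzra_prevalence_pct, 100 * nrow(m) / 2000)
  # prevalence arithmetic holds before rounding
  expect_equal(rep1$hazardous_prevalence_pct / 100 * rep1$n_bzra_patients,
               rep1$n_hazardous)
  expect_true(all(rep1$hazardous_by_hospital_pct >= 0 &
                    rep1$hazardous_by_hospital_pct <= 100))
  # report generation is pure: identical inputs, identical output
  rep2 <- summarize_cohort(cc, m, lab, reg, n_total_outpatients = 2000)
  expect_identical(rep1, rep2)
})

test_that("over-indication drug ranking reflects who is flagged", {
  r_none <- make_records("2018-02-01", "clonazepam", 0.5, 10,
                         diagnoses = "G40.1")
  pd <- flag_over_indication_by_drug(r_none, reg)
  expect_equal(nrow(over_indication_report(pd, r_none)), 0L)

  r_one <- make_records("2018-02-01", "clonazepam", 0.5, 10,
                        diagnoses = "F32.1")
  pd1 <- flag_over_indication_by_drug(r_one, reg)
  rk <- over_indication_report(pd1, r_one)
  expect_equal(rk$drug_id, "clonazepam")
  expect_equal(rk$pct_of_over_indication, 100)
  expect_match(rk$top_blocks, "F30-F39")
})
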
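reg <- default_registry

test_that("daily arrays accumulate converted doses over coverage intervals", {
  rec <- make_records("2018-01-06", "clonazepam", 0.5, 10)
  rec$visit_date <- as.Date(rec$visit_date)
  arr <- build_daily_array(rec, reg, 2018L)
  expect_length(arr, 365L)
  expect_equal(sum(arr > 0), 10L)
  expect_equal(unique(arr[arr > 0]), 10)
  expect_equal(sum(arr), 100)

  # no records: all-zero array
  expect_identical(build_daily_array(rec[0, ], reg, 2018L), numeric(365))

  # overlapping prescriptions stack
  rec2 <- make_records(c("2018-05-01", "2018-05-01"), "zolpidem", 20, 5)
  rec2$visit_date <- as.Date(rec2$visit_date)
  arr2 <- build_daily_array(rec2, reg, 2018L)
  expect_equal(sum(arr2 > 0), 5L)
  expect_equal(unique(arr2[arr2 > 0]), 20)
})

test_that("leap years get a 366-day array", {
  rec <- make_records("2020-12-31", "diazepam", 10, 1)
  rec$visit_date <- as.Date(rec$visit_date)
  arr <- build_daily_array(rec, reg, 2020L)
  expect_length(arr, 366L)
  expect_equal(arr[366], 10)
})

test_that("windowed maximum average matches direct cases", {
  expect_equal(max_window_average(numeric(365), 90), 0)
  expect_equal(max_window_average(rep(10, 365), 90), 10)
  x <- numeric(365); x[100:129] <- 90
  expect_equal(max_window_average(x, 90), 30)
  expect_error(max_window_average(x, 0), "window_days")
})

test_that("windowed maximum average equals the brute-force oracle", {
  set.seed(101)
  for (i in 1:300) {
    n <- sample(90:366, 1)
    x <- numeric(n)
    nuse <- sample(0:n, 1)
    x[sample(n, nuse)] <- round(stats::rlnorm(nuse, 2, 1), 3)
    w <- sample(c(1L, 7L, 30L, 90L), 1)
    expect_equal(max_window_average(x, w), oracle_window_max(x, w))
  }
})

test_that("gap-tolerant episodes merge and break per the tolerance", {
  x <- numeric(365)
  x[1:10] <- 1; x[14:20] <- 1          # 3-day gap at days 11-13
  expect_equal(detect_max_run(x, 3), 20L)
  y <- numeric(365)
  y[1:10] <- 1; y[15:20] <- 1          # 4-day gap
  expect_equal(detect_max_run(y, 3), 10L)
  expect_equal(detect_max_run(numeric(365), 3), 0L)
})

test_that("episode detection equals the state-machine oracle and is monotone in the gap", {
  set.seed(202)
  for (i in 1:300) {
    n <- sample(30:366, 1)
    x <- as.numeric(stats::runif(n) < stats::runif(1, 0.05, 0.6))
    runs <- vapply(c(0L, 1L, 2L, 3L, 5L), function(g) {
      r <- detect_max_run(x, g)
      expect_equal(r, oracle_max_run(x, g))
      r
    }, integer(1))
    expect_true(all(diff(runs) >= 0))  # nondecreasing in max_gap
    # gap 0 equals the longest unbridged run
    rl <- rle(x > 0)
    expect_equal(runs[1], max(c(0L, rl$lengths[rl$values])))
  }
})

test_that("per-patient metrics assemble correctly", {
  rec <- make_records("2018-03-01", "clonazepam", 0.5, 10)
  rec$visit_date <- as.Date(rec$visit_date)
  m <- compute_metrics(rec, reg, 2018L)
  expect_equal(m$max_window_avg_dme, 100 / 90)
  expect_equal(m$total_dme, 100)
  expect_equal(m$max_continuous_days, 10L)
  expect_equal(m$total_days_of_use, 10L)
  expect_equal(m$n_visits, 1L)
  expect_equal(m$n_distinct_doctors, 1L)
  expect_equal(m$average_daily_dme, 10)

  two <- make_records(c("2018-03-01", "2018-06-01"), "diazepam", 5, 7,
                      doctor = c("D1", "D2"))
  two$visit_date <- as.Date(two$visit_date)
  m2 <- compute_metrics(two, reg, 2018L)
  expect_equal(m2$n_visits, 2L)
  expect_equal(m2$n_distinct_doctors, 2L)

  same_doc <- make_records(c("2018-03-01", "2018-06-01"), "diazepam", 5, 7,
                           doctor = "D1")
  same_doc$visit_date <- as.Date(same_doc$visit_date)
  m3 <- compute_metrics(same_doc, reg, 2018L)
  expect_equal(m3$n_visits, 2L)
  expect_equal(m3$n_distinct_doctors, 1L)
  expect_error(compute_metrics(two[0, ], reg, 2018L))
})

test_that("array totals conserve prescription totals on synthetic cohorts", {
  rec <- generate_cohort(cohort_config(n_patients = 150, seed = 5))
  cc <- clean_cohort(rec, reg)
  metrics <- compute_exposure(cc, reg)
  r <- cc$records
  expected <- tapply(to_dme(reg, r$drug_id, r$daily_dose_mg) *
                       r$days_supplied, r$patient_id, sum)
  expect_equal(metrics$total_dme,
               as.numeric(expected[metrics$patient_id]),
               tolerance = 1e-9)
})

test_that("adding a prescription never decreases any exposure metric", {
  set.seed(303)
  for (i in 1:25) {
    n <- sample(1:5, 1)
    rec <- make_records(
      visit = format(as.Date("2018-01-01") + sample(0:330, n + 1)),
      drug = sample(reg$drugs$drug_id, n + 1, replace = TRUE),
      dose = round(stats::runif(n + 1, 0.5, 20), 2),
      days = sample(1:30, n + 1, replace = TRUE))
    rec$visit_date <- as.Date(rec$visit_date)
    m_small <- compute_metrics(rec[1:n, ], reg, 2018L)
    m_big <- compute_metrics(rec, reg, 2018L)
    tol <- 1e-9 * (1 + abs(m_small$max_window_avg_dme))
    for (col in c("total_dme", "max_window_avg_dme", "total_days_of_use",
                  "max_continuous_days"))
      expect_true(m_big[[col]] >= m_small[[col]] - tol, info = col)
  }
})
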
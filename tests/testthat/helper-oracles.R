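# Independent brute-force oracles for the exposure statistics. These stay
# deliberately naive: the window oracle scans every window with sum(); the
# episode oracle walks the days with an explicit state machine.

oracle_window_max <- function(x, w) {
  n <- length(x)
  best <- 0
  for (i in 1:(n - w + 1)) best <- max(best, sum(x[i:(i + w - 1)]))
  best / w
}

oracle_max_run <- function(x, max_gap) {
  best <- 0L
  run_start <- NA_integer_
  last_use <- NA_integer_
  for (d in seq_along(x)) {
    if (x[d] > 0) {
      if (is.na(run_start) || d - last_use - 1L > max_gap) run_start <- d
      last_use <- d
      best <- max(best, last_use - run_start + 1L)
    }
  }
  best
}

# one-patient record table builder
make_records <- function(visit, drug, dose, days, patient = "P1",
                         hospital = "H01", doctor = "H01_D01",
                         diagnoses = "G47.0", gender = "female", age = 40) {
  n <- max(length(visit), length(drug), length(dose), length(days))
  data.frame(patient_id = rep_len(patient, n),
             hospital_id = rep_len(hospital, n),
             doctor_id = rep_len(doctor, n),
             visit_date = rep_len(visit, n),
             drug_id = rep_len(drug, n),
             daily_dose_mg = rep_len(dose, n),
             days_supplied = rep_len(as.integer(days), n),
             diagnoses = rep_len(diagnoses, n),
             gender = rep_len(gender, n),
             age_years = rep_len(as.integer(age), n),
             stringsAsFactors = FALSE)
}

default_registry <- load_registry()
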
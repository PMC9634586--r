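#' Build a patient's daily DME dose array
#'
#' Accumulates a patient's prescriptions into a vector of total dispensed
#' diazepam milligram equivalents attributable to each calendar day of the
#' study year (index 1 = Jan 1). Each record contributes its daily dose,
#' converted to DME, to every day of its coverage interval
#' \code{[visit_date, visit_date + days_supplied - 1]}; overlapping
#' prescriptions stack (daily doses sum). Stockpiling through early refills
#' is therefore visible as elevated daily totals and is handled downstream
#' by the windowed-average maximum, not by carrying supply forward.
#'
#' @param records one patient's prescription records, truncated to the year.
#' @param registry a \code{dme_registry}.
#' @param year the study calendar year.
#' @return numeric vector of length 365/366 of nonnegative daily DME.
#' @export
build_daily_array <- function(records, registry, year) {
  nd <- .year_days(year)
  x <- numeric(nd)
  if (nrow(records) == 0L) return(x)
  start <- .day_of_year(as.Date(records$visit_date), year)
  stopifnot(all(start >= 1L), all(start + records$days_supplied - 1L <= nd))
  dme <- to_dme(registry, records$drug_id, records$daily_dose_mg)
  for (i in seq_along(start)) {
    idx <- start[i]:(start[i] + records$days_supplied[i] - 1L)
    x[idx] <- x[idx] + dme[i]
  }
  x
}

#' Maximum windowed average daily dose
#'
#' The largest mean daily DME over any contiguous window of
#' \code{window_days} calendar days. Days without use count as zero in the
#' denominator, so the statistic measures the densest sustained exposure
#' rather than the dose on days of use. With the default 90-day window this
#' is the "maximum averaged daily DME" statistic whose threshold of 40
#' defines overdose use.
#'
#' @param x daily dose array (numeric vector).
#' @param window_days positive window length, at most \code{length(x)}.
#' @return the maximum window mean (0 for an all-zero array).
#' @export
max_window_average <- function(x, window_days = 90L) {
  stopifnot(window_days >= 1L, window_days <= length(x))
  cs <- c(0, cumsum(x))
  n <- length(x)
  w <- as.integer(window_days)
  max(cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]) / w
}

#' Longest gap-tolerant continuous-use episode
#'
#' Over the binary use vector (a day is a use day iff its daily DME is
#' positive), use runs separated by at most \code{max_gap} consecutive
#' non-use days are merged into one episode. Returns the calendar span of
#' the longest merged episode — first to last use day inclusive, bridged gap
#' days counted — or 0 if there are no use days. The default tolerance of 3
#' days reflects the 72-hour horizon over which withdrawal symptoms peak
#' after cessation.
#'
#' @param x daily dose array (numeric vector) or logical use vector.
#' @param max_gap nonnegative number of bridgeable non-use days.
#' @return integer episode length in days.
#' @export
detect_max_run <- function(x, max_gap = 3L) {
  stopifnot(max_gap >= 0L)
  use <- which(x > 0)
  if (length(use) == 0L) return(0L)
  # split the sorted use days where the gap exceeds the tolerance
  brk <- which(diff(use) > max_gap + 1L)
  starts <- use[c(1L, brk + 1L)]
  ends <- use[c(brk, length(use))]
  max(ends - starts + 1L)
}

#' Per-patient exposure metrics
#'
#' Assembles the exposure statistics reported per patient: the maximum
#' 90-day-window average daily DME, total yearly DME, longest gap-tolerant
#' continuous-use episode, total days of use (days with positive DME),
#' number of dispensing visits (distinct visit-date/doctor pairs), number of
#' distinct doctors, and average daily DME on days of use.
#'
#' @param records one patient's prescription records (nonempty, truncated).
#' @param registry a \code{dme_registry}.
#' @param year study year.
#' @param window_days window for the dose maximum (days).
#' @param max_gap episode gap tolerance (days).
#' @return one-row data frame of metrics.
#' @export
compute_metrics <- function(records, registry, year,
                            window_days = 90L, max_gap = 3L) {
  stopifnot(nrow(records) >= 1L)
  arr <- build_daily_array(records, registry, year)
  total_days <- sum(arr > 0)
  data.frame(
    patient_id = records$patient_id[1],
    max_window_avg_dme = max_window_average(arr, window_days),
    total_dme = sum(arr),
    max_continuous_days = detect_max_run(arr, max_gap),
    total_days_of_use = total_days,
    n_visits = nrow(unique(records[, c("visit_date", "doctor_id")])),
    n_distinct_doctors = length(unique(records$doctor_id)),
    average_daily_dme = if (total_days > 0) sum(arr) / total_days else 0,
    stringsAsFactors = FALSE
  )
}

#' Exposure metrics for a whole cohort
#'
#' Applies [compute_metrics()] to every patient of a clean cohort and
#' attaches the patient's hospital (hospital of first dispensing) and
#' demographics.
#'
#' @param cohort a \code{clean_cohort} from [read_prescriptions()] or
#'   [clean_cohort()].
#' @param registry a \code{dme_registry}.
#' @inheritParams compute_metrics
#' @return data frame, one row per patient: metrics plus hospital_id,
#'   gender, age_years and the complete_covariates flag.
#' @export
compute_exposure <- function(cohort, registry = load_registry(),
                             window_days = 90L, max_gap = 3L) {
  stopifnot(inherits(cohort, "clean_cohort"))
  rec <- cohort$records
  year <- cohort$study_year
  nd <- .year_days(year)
  if (nrow(rec) == 0L)
    return(data.frame(patient_id = character(0)))

  start <- .day_of_year(rec$visit_date, year)
  dme <- to_dme(registry, rec$drug_id, rec$daily_dose_mg)
  pid <- rec$patient_id
  groups <- split(seq_len(nrow(rec)), pid)

  out <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    i <- groups[[g]]
    arr <- numeric(nd)
    for (k in i) {
      idx <- start[k]:(start[k] + rec$days_supplied[k] - 1L)
      arr[idx] <- arr[idx] + dme[k]
    }
    total_days <- sum(arr > 0)
    out[[g]] <- c(max_window_average(arr, window_days), sum(arr),
                  detect_max_run(arr, max_gap), total_days,
                  nrow(unique(rec[i, c("visit_date", "doctor_id")])),
                  length(unique(rec$doctor_id[i])),
                  if (total_days > 0) sum(arr) / total_days else 0)
  }
  m <- do.call(rbind, out)
  res <- data.frame(
    patient_id = names(groups),
    max_window_avg_dme = m[, 1], total_dme = m[, 2],
    max_continuous_days = as.integer(m[, 3]),
    total_days_of_use = as.integer(m[, 4]),
    n_visits = as.integer(m[, 5]), n_distinct_doctors = as.integer(m[, 6]),
    average_daily_dme = m[, 7],
    stringsAsFactors = FALSE
  )
  hosp <- .patient_hospital(rec)
  res$hospital_id <- hosp$hospital_id[match(res$patient_id, hosp$patient_id)]
  first <- rec[!duplicated(rec$patient_id), ]
  j <- match(res$patient_id, first$patient_id)
  res$gender <- first$gender[j]
  res$age_years <- first$age_years[j]
  res$complete_covariates <- first$complete_covariates[j]
  rownames(res) <- NULL
  res
}
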
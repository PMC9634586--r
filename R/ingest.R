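#' Prescription CSV column names
#'
#' The exact input columns expected by [read_prescriptions()] and written by
#' [write_cohort()].
#' @export
prescription_columns <- c(
  "patient_id", "hospital_id", "doctor_id", "visit_date", "drug_id",
  "daily_dose_mg", "days_supplied", "diagnoses", "gender", "age_years")

.year_days <- function(year) {
  as.integer(as.Date(sprintf("%d-12-31", year)) -
               as.Date(sprintf("%d-01-01", year))) + 1L
}

.day_of_year <- function(dates, year) {
  as.integer(dates - as.Date(sprintf("%d-01-01", year))) + 1L
}

#' Truncate prescriptions to the study year
#'
#' Coverage of a record is the closed interval
#' \code{[visit_date, visit_date + days_supplied - 1]} in calendar days.
#' Supplies that would overrun Dec 31 of the study year are shortened so
#' coverage ends on Dec 31; the operation is idempotent.
#'
#' @param records a prescription data frame (see [prescription_columns]).
#' @param year the study calendar year.
#' @return the records with \code{days_supplied} truncated.
#' @export
truncate_to_year <- function(records, year) {
  if (nrow(records) == 0L) return(records)
  d <- .day_of_year(as.Date(records$visit_date), year)
  stopifnot(all(d >= 1L & d <= .year_days(year)))
  remaining <- .year_days(year) - d + 1L
  records$days_supplied <- pmin(as.integer(records$days_supplied), remaining)
  records
}

#' Read and validate prescription dispensing records
#'
#' Reads the documented CSV dialect, applies two tiers of exclusion, and
#' scopes records to the study year. Hard exclusions remove records that are
#' unusable for exposure reconstruction: unknown drug, unparseable or
#' out-of-year visit date, non-positive daily dose or days supplied. Soft
#' exclusions do not remove records: patients with missing gender, age or
#' diagnosis information are retained for descriptive statistics (with an
#' "unknown" category) but flagged for exclusion from the regression,
#' mirroring the usual practice in prescription-database studies of deleting
#' incomplete observations only from the model.
#'
#' @param path CSV file path.
#' @param registry a \code{dme_registry}; records for drugs outside it are
#'   excluded (scope is the twelve benzodiazepine receptor agonists).
#' @param year study year; defaults to the modal year of the visit dates.
#' @return an object of class \code{clean_cohort}: list with \code{records}
#'   (validated, year-truncated data frame with a \code{Date} visit_date and
#'   a logical \code{complete_covariates} patient flag), \code{excluded_count},
#'   \code{exclusion_reasons} (named integer vector), \code{soft_excluded_patients}
#'   (patient ids lacking gender/age/diagnosis), and \code{study_year}.
#' @export
read_prescriptions <- function(path, registry = load_registry(), year = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(prescription_columns, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(raw) == 0L) {
    warning("empty prescription file: ", path)
    return(.clean_cohort(raw, integer(0), year %||% NA_integer_))
  }
  clean_cohort(raw, registry = registry, year = year)
}

#' Validate an in-memory prescription data frame
#'
#' The validation half of [read_prescriptions()], usable on records produced
#' by [generate_cohort()] without a file round-trip.
#'
#' @inheritParams read_prescriptions
#' @param records data frame with the columns in [prescription_columns].
#' @return a \code{clean_cohort} (see [read_prescriptions()]).
#' @export
clean_cohort <- function(records, registry = load_registry(), year = NULL) {
  stopifnot(all(prescription_columns %in% names(records)))
  n <- nrow(records)
  dates <- as.Date(as.character(records$visit_date), format = "%Y-%m-%d",
                   optional = TRUE)
  if (is.null(year)) {
    yrs <- as.integer(format(dates, "%Y"))
    year <- as.integer(names(sort(table(yrs), decreasing = TRUE))[1])
  }
  dose <- suppressWarnings(as.numeric(records$daily_dose_mg))
  dur <- suppressWarnings(as.integer(records$days_supplied))

  reason <- rep(NA_character_, n)
  in_year <- !is.na(dates) &
    dates >= as.Date(sprintf("%d-01-01", year)) &
    dates <= as.Date(sprintf("%d-12-31", year))
  reason[is.na(reason) & (is.na(dates) | !in_year)] <- "bad_date"
  reason[is.na(reason) &
           !(tolower(records$drug_id) %in% registry$drugs$drug_id)] <-
    "unknown_drug"
  reason[is.na(reason) & (is.na(dose) | dose <= 0)] <- "nonpositive_dose"
  reason[is.na(reason) & (is.na(dur) | dur <= 0)] <- "nonpositive_duration"

  keep <- is.na(reason)
  rec <- records[keep, prescription_columns]
  rec$visit_date <- dates[keep]
  rec$drug_id <- tolower(rec$drug_id)
  rec$daily_dose_mg <- dose[keep]
  rec$days_supplied <- dur[keep]
  rec$age_years <- suppressWarnings(as.integer(rec$age_years))
  rec$gender[!rec$gender %in% c("female", "male")] <- NA_character_
  rec <- truncate_to_year(rec, year)
  rownames(rec) <- NULL

  # soft exclusion: any missing gender/age/diagnosis anywhere in the year
  miss <- is.na(rec$gender) | is.na(rec$age_years) |
    is.na(rec$diagnoses) | !nzchar(rec$diagnoses)
  soft <- sort(unique(rec$patient_id[miss]))
  rec$complete_covariates <- !(rec$patient_id %in% soft)

  .clean_cohort(rec, table(reason[!keep]), year, soft)
}

.clean_cohort <- function(rec, reasons, year, soft = character(0)) {
  reasons <- if (length(reasons)) {
    r <- as.integer(reasons); names(r) <- names(reasons); r
  } else integer(0)
  structure(list(records = rec,
                 excluded_count = sum(reasons),
                 exclusion_reasons = reasons,
                 soft_excluded_patients = soft,
                 study_year = as.integer(year)),
            class = "clean_cohort")
}

#' @export
print.clean_cohort <- function(x, ...) {
  cat("Clean prescription cohort, study year", x$study_year, "\n")
  cat(" ", nrow(x$records), "records retained,",
      length(unique(x$records$patient_id)), "patients\n")
  cat(" ", x$excluded_count, "records hard-excluded")
  if (x$excluded_count > 0)
    cat(" (", paste(names(x$exclusion_reasons), x$exclusion_reasons,
                    sep = ": ", collapse = ", "), ")", sep = "")
  cat("\n ", length(x$soft_excluded_patients),
      "patients flagged for regression exclusion (missing covariates)\n")
  invisible(x)
}

# hospital of first dispensing, per patient (multi-hospital patients are
# assigned to the hospital where they were first seen)
.patient_hospital <- function(records) {
  ord <- order(records$patient_id, records$visit_date)
  r <- records[ord, c("patient_id", "hospital_id")]
  r[!duplicated(r$patient_id), ]
}
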
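#' Overdose-use flag
#'
#' A patient is an overdose user when their maximum 90-day-window average
#' daily dose exceeds the threshold, strictly ("more than 40" DME/day).
#'
#' @param max_window_avg_dme numeric vector of window-maximum averages.
#' @param dme_threshold threshold in DME/day.
#' @return logical vector.
#' @export
flag_overdose <- function(max_window_avg_dme, dme_threshold = 40) {
  max_window_avg_dme > dme_threshold
}

#' Long-term-use flag
#'
#' A patient is a long-term user when their longest gap-tolerant
#' continuous-use episode reaches the day threshold. The cutoff is
#' inclusive: exactly three back-to-back 30-day prescriptions (90 covered
#' days) qualify, consistent with the rationale of requiring at least three
#' prescriptions in a year under 30-day prescription length limits.
#'
#' @param max_continuous_days integer vector of episode lengths.
#' @param day_threshold cutoff in days.
#' @return logical vector.
#' @export
flag_long_term <- function(max_continuous_days, day_threshold = 90L) {
  max_continuous_days >= day_threshold
}

#' Hazard labels for a cohort
#'
#' Hazardous use is the conjunction of overdose use and long-term use.
#'
#' @param metrics per-patient exposure metrics (from [compute_exposure()]).
#' @param dme_threshold overdose threshold (DME/day, strict).
#' @param day_threshold long-term threshold (days, inclusive).
#' @param max_gap gap tolerance recorded for provenance.
#' @return data frame (patient_id, overdose, long_term, hazardous) with the
#'   thresholds attached as the \code{"thresholds"} attribute.
#' @export
flag_hazardous <- function(metrics, dme_threshold = 40, day_threshold = 90L,
                           max_gap = 3L) {
  out <- data.frame(
    patient_id = metrics$patient_id,
    overdose = flag_overdose(metrics$max_window_avg_dme, dme_threshold),
    long_term = flag_long_term(metrics$max_continuous_days, day_threshold),
    stringsAsFactors = FALSE
  )
  out$hazardous <- out$overdose & out$long_term
  attr(out, "thresholds") <- list(dme_threshold = dme_threshold,
                                  day_threshold = day_threshold,
                                  max_gap = max_gap)
  out
}

.split_diagnoses <- function(s) {
  s <- s[!is.na(s) & nzchar(s)]
  unique(trimws(unlist(strsplit(s, ";", fixed = TRUE))))
}

.code_matches_any <- function(codes, prefixes) {
  if (length(codes) == 0L || length(prefixes) == 0L) return(FALSE)
  any(vapply(prefixes, function(p) any(startsWith(codes, p)), logical(1)))
}

#' Over-indication flags
#'
#' A patient is an over-indication user when none of their recorded
#' diagnoses over the year matches (by ICD-10 prefix) any approved
#' indication of any drug dispensed to them — i.e. not a single dispensed
#' drug is justified by a single recorded diagnosis. Diagnoses are pooled
#' across all visits of the year, not matched visit by visit. Patients with
#' no usable diagnosis data return \code{NA}.
#'
#' The per-drug variant reports, for each patient-drug pair, whether that
#' particular drug is unjustified by every pooled diagnosis; it powers the
#' drug-level over-indication ranking.
#'
#' @param records a cohort's prescription records.
#' @param registry a \code{dme_registry} (its \code{indications} map is used).
#' @return \code{flag_over_indication}: data frame (patient_id,
#'   over_indication). \code{flag_over_indication_by_drug}: data frame
#'   (patient_id, drug_id, drug_over_indication).
#' @export
flag_over_indication <- function(records, registry = load_registry()) {
  per_drug <- flag_over_indication_by_drug(records, registry)
  agg <- tapply(per_drug$drug_over_indication, per_drug$patient_id,
                function(v) if (anyNA(v)) NA else all(v))
  data.frame(patient_id = names(agg),
             over_indication = as.logical(agg),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname flag_over_indication
#' @export
flag_over_indication_by_drug <- function(records, registry = load_registry()) {
  missing_drugs <- setdiff(unique(records$drug_id), names(registry$indications))
  if (length(missing_drugs))
    stop("no indication entry for drug(s): ",
         paste(missing_drugs, collapse = ", "), call. = FALSE)
  diag_by_pat <- tapply(records$diagnoses, records$patient_id,
                        .split_diagnoses, simplify = FALSE)
  pairs <- unique(records[, c("patient_id", "drug_id")])
  pat_idx <- match(pairs$patient_id, names(diag_by_pat))
  drug_ind <- registry$indications[pairs$drug_id]
  flag <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    codes <- diag_by_pat[[pat_idx[i]]]
    if (length(codes) == 0L) { flag[i] <- NA; next }
    flag[i] <- !.code_matches_any(codes, drug_ind[[i]])
  }
  data.frame(patient_id = pairs$patient_id, drug_id = pairs$drug_id,
             drug_over_indication = flag, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' All classification labels for a cohort
#'
#' Convenience wrapper joining [flag_hazardous()] and
#' [flag_over_indication()] for a clean cohort.
#'
#' @param cohort a \code{clean_cohort}.
#' @param metrics per-patient metrics (computed if omitted).
#' @inheritParams flag_hazardous
#' @param registry a \code{dme_registry}.
#' @return data frame (patient_id, overdose, long_term, hazardous,
#'   over_indication), thresholds attached as attribute.
#' @export
classify_cohort <- function(cohort, metrics = NULL,
                            registry = load_registry(),
                            dme_threshold = 40, day_threshold = 90L,
                            max_gap = 3L, window_days = 90L) {
  if (is.null(metrics))
    metrics <- compute_exposure(cohort, registry, window_days, max_gap)
  labels <- flag_hazardous(metrics, dme_threshold, day_threshold, max_gap)
  oi <- flag_over_indication(cohort$records, registry)
  labels$over_indication <-
    oi$over_indication[match(labels$patient_id, oi$patient_id)]
  labels
}
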
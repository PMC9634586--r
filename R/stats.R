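# ICD-10 reporting blocks used for diagnosis distributions: the mental and
# behavioural chapter in decades, plus epilepsy and sleep disorders.
.diagnosis_blocks <- function() {
  list("F01-F09" = sprintf("F0%d", 1:9),
       "F10-F19" = sprintf("F1%d", 0:9),
       "F20-F29" = sprintf("F2%d", 0:9),
       "F30-F39" = sprintf("F3%d", 0:9),
       "F40-F49" = sprintf("F4%d", 0:9),
       "F50-F59" = sprintf("F5%d", 0:9),
       "F60-F69" = sprintf("F6%d", 0:9),
       "F70-F79" = sprintf("F7%d", 0:9),
       "F80-F89" = sprintf("F8%d", 0:9),
       "F90-F98" = sprintf("F9%d", 0:8),
       "F99-F99" = "F99",
       "G40-G41" = c("G40", "G41"),
       "G47" = "G47")
}

.age_group <- function(age) {
  cut(age, breaks = c(-Inf, 17, 64, Inf),
      labels = c("<18", "18-64", ">=65"))
}

.med_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE,
                       type = 7)
  c(q1 = q[1], median = q[2], q3 = q[3])
}

#' Drug-class usage category for each patient
#'
#' Classifies each patient by the set of drug classes dispensed to them over
#' the year: benzodiazepines only, Z-drugs only, or both.
#'
#' @param records cohort prescription records.
#' @param registry a \code{dme_registry}.
#' @return data frame (patient_id, drug_use) with drug_use a factor with
#'   levels \code{BZD_only}, \code{Z_only}, \code{both}.
#' @export
classify_drug_use <- function(records, registry = load_registry()) {
  cls <- factor(registry$drugs$drug_class[.lookup_drug(registry,
                                                       records$drug_id)],
                levels = c("BZD", "Z_DRUG"))
  has <- table(records$patient_id, cls) > 0
  use <- ifelse(has[, "BZD"] & has[, "Z_DRUG"], "both",
                ifelse(has[, "BZD"], "BZD_only", "Z_only"))
  data.frame(patient_id = rownames(has),
             drug_use = factor(use, levels = c("BZD_only", "Z_only", "both")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' DDD consumption totals
#'
#' Total consumption in WHO defined daily doses, grouped by hospital and
#' drug class (and optionally drug). The DDD total of a record is
#' \code{daily_dose_mg * days_supplied / ddd_mg}.
#'
#' @param records cohort prescription records (year-truncated).
#' @param registry a \code{dme_registry}.
#' @param by grouping: \code{"class"} (hospital x drug class) or
#'   \code{"drug"} (hospital x drug).
#' @return data frame of group DDD totals.
#' @export
ddd_consumption <- function(records, registry = load_registry(),
                            by = c("class", "drug")) {
  by <- match.arg(by)
  if (nrow(records) == 0L)
    return(data.frame(hospital_id = character(0), group = character(0),
                      ddd = numeric(0)))
  ddd <- to_ddd(registry, records$drug_id,
                records$daily_dose_mg * records$days_supplied)
  grp <- if (by == "class")
    registry$drugs$drug_class[.lookup_drug(registry, records$drug_id)]
  else records$drug_id
  agg <- stats::aggregate(ddd, by = list(hospital_id = records$hospital_id,
                                         group = grp), FUN = sum)
  names(agg)[3] <- "ddd"
  agg[order(agg$hospital_id, agg$group), , drop = FALSE]
}

#' Classical two-or-more-group comparison
#'
#' Chooses the test the data type calls for: chi-square for categorical
#' responses (Yates continuity correction only for 2x2 tables), Wilcoxon
#' rank-sum for a continuous response across two groups, Kruskal-Wallis for
#' three or more.
#'
#' @param x response: numeric (continuous) or factor/character (categorical).
#' @param g grouping vector (2 or more nonempty groups).
#' @param correct_2x2 apply Yates correction to 2x2 tables.
#' @return list of class \code{group_test} with \code{statistic},
#'   \code{p_value}, \code{test_name}, \code{group_sizes}.
#' @export
compare_groups <- function(x, g, correct_2x2 = TRUE) {
  g <- factor(g)
  sizes <- table(g)
  if (any(sizes == 0L) || nlevels(g) < 2L)
    stop("need at least 2 nonempty groups", call. = FALSE)
  if (is.numeric(x)) {
    if (nlevels(g) == 2L) {
      ht <- stats::wilcox.test(x ~ g, exact = FALSE)
      name <- "wilcoxon_rank"
    } else {
      ht <- stats::kruskal.test(x, g)
      name <- "kruskal_wallis"
    }
  } else {
    tab <- table(x, g)
    ht <- suppressWarnings(
      stats::chisq.test(tab, correct = correct_2x2 && all(dim(tab) == 2L)))
    name <- "chi_square"
  }
  structure(list(statistic = unname(ht$statistic),
                 p_value = unname(ht$p.value),
                 test_name = name,
                 group_sizes = as.integer(sizes)),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (groups: %s)\n",
              x$test_name, x$statistic, x$p_value,
              paste(x$group_sizes, collapse = "/")))
  invisible(x)
}

#' Drug ranking among over-indication users
#'
#' For each drug, the share of over-indication patients who were prescribed
#' that drug without a matching indication, with the ICD-10 block
#' distribution of those patients' diagnoses.
#'
#' @param per_drug output of [flag_over_indication_by_drug()].
#' @param records cohort prescription records (for pooled diagnoses).
#' @return data frame (drug_id, n_patients, pct_of_over_indication,
#'   top_blocks), sorted by share, empty if no over-indication patients.
#' @export
over_indication_report <- function(per_drug, records) {
  pat_flag <- tapply(per_drug$drug_over_indication, per_drug$patient_id,
                     function(v) if (anyNA(v)) NA else all(v))
  oi_patients <- names(pat_flag)[!is.na(pat_flag) & pat_flag]
  if (length(oi_patients) == 0L)
    return(data.frame(drug_id = character(0), n_patients = integer(0),
                      pct_of_over_indication = numeric(0),
                      top_blocks = character(0)))
  sub <- per_drug[per_drug$patient_id %in% oi_patients &
                    per_drug$drug_over_indication, ]
  counts <- sort(table(sub$drug_id), decreasing = TRUE)
  diag_by_pat <- tapply(records$diagnoses, records$patient_id,
                        .split_diagnoses, simplify = FALSE)
  blocks <- .diagnosis_blocks()
  top_blocks <- vapply(names(counts), function(d) {
    pats <- unique(sub$patient_id[sub$drug_id == d])
    codes <- unlist(diag_by_pat[pats], use.names = FALSE)
    hit <- vapply(blocks, function(pr) {
      sum(vapply(pats, function(p)
        .code_matches_any(diag_by_pat[[p]], pr), logical(1)))
    }, numeric(1))
    hit <- sort(hit[hit > 0], decreasing = TRUE)
    paste(sprintf("%s (%.1f%%)", names(hit)[seq_len(min(3, length(hit)))],
                  100 * hit[seq_len(min(3, length(hit)))] / length(pats)),
          collapse = ", ")
  }, character(1))
  data.frame(drug_id = names(counts),
             n_patients = as.integer(counts),
             pct_of_over_indication = 100 * as.integer(counts) /
               length(oi_patients),
             top_blocks = top_blocks,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cohort descriptive report
#'
#' Produces the descriptive outputs of a prescription-database screening:
#' cohort size and demographics, diagnosis-block distribution (a patient
#' with diagnoses in several blocks counts in each), per-metric medians and
#' IQRs (linear-interpolation quartiles) overall and per hospital, hazardous
#' and over-indication prevalence, drug-class usage proportions, DDD
#' consumption, per-drug usage shares by hazard group, and the
#' over-indication drug ranking.
#'
#' @param cohort a \code{clean_cohort}.
#' @param metrics per-patient exposure metrics.
#' @param labels per-patient labels from [classify_cohort()].
#' @param registry a \code{dme_registry}.
#' @param n_total_outpatients optional denominator for the prescription-
#'   prevalence headline (count of all out-patients, treated or not).
#' @return object of class \code{cohort_report} (a list of tables).
#' @export
summarize_cohort <- function(cohort, metrics, labels,
                             registry = load_registry(),
                             n_total_outpatients = NULL) {
  stopifnot(nrow(metrics) >= 1L)
  rec <- cohort$records
  n <- nrow(metrics)

  demo <- table(gender = ifelse(is.na(metrics$gender), "unknown",
                                metrics$gender),
                age_group = ifelse(is.na(metrics$age_years), "unknown",
                                   as.character(.age_group(metrics$age_years))))

  diag_by_pat <- tapply(rec$diagnoses, rec$patient_id, .split_diagnoses,
                        simplify = FALSE)
  blocks <- .diagnosis_blocks()
  block_counts <- vapply(blocks, function(pr)
    sum(vapply(diag_by_pat, .code_matches_any, logical(1), prefixes = pr)),
    numeric(1))

  metric_cols <- c("max_window_avg_dme", "total_dme", "max_continuous_days",
                   "total_days_of_use", "n_visits", "n_distinct_doctors",
                   "average_daily_dme")
  overall <- t(vapply(metric_cols, function(m) .med_iqr(metrics[[m]]),
                      numeric(3)))
  by_hosp <- lapply(split(metrics, metrics$hospital_id), function(d)
    t(vapply(metric_cols, function(m) .med_iqr(d[[m]]), numeric(3))))

  lab <- labels[match(metrics$patient_id, labels$patient_id), ]
  haz_overall <- mean(lab$hazardous)
  haz_by_hosp <- tapply(lab$hazardous, metrics$hospital_id, mean)
  oi_overall <- mean(lab$over_indication, na.rm = TRUE)

  du <- classify_drug_use(rec, registry)
  class_prop <- prop.table(table(du$drug_use))

  per_drug_flags <- flag_over_indication_by_drug(rec, registry)
  drug_by_group <- local({
    pd <- unique(rec[, c("patient_id", "drug_id")])
    pd$hazardous <- lab$hazardous[match(pd$patient_id, lab$patient_id)]
    ng <- table(lab$hazardous)
    tab <- table(pd$drug_id, pd$hazardous)
    sweep(tab, 2, as.numeric(ng[colnames(tab)]), "/") * 100
  })

  structure(list(
    n_total_outpatients = n_total_outpatients,
    n_bzra_patients = n,
    bzra_prevalence_pct = if (!is.null(n_total_outpatients))
      100 * n / n_total_outpatients else NA_real_,
    demographics = demo,
    diagnosis_blocks = data.frame(block = names(block_counts),
                                  n = as.integer(block_counts),
                                  pct = 100 * block_counts / n,
                                  row.names = NULL),
    metric_summary = overall,
    metric_summary_by_hospital = by_hosp,
    hazardous_prevalence_pct = 100 * haz_overall,
    hazardous_by_hospital_pct = 100 * haz_by_hosp,
    n_hazardous = sum(lab$hazardous),
    over_indication_pct = 100 * oi_overall,
    drug_class_use_pct = 100 * class_prop,
    ddd_by_hospital_class = ddd_consumption(rec, registry, "class"),
    drug_use_by_hazard_group_pct = drug_by_group,
    over_indication_ranking = over_indication_report(per_drug_flags, rec),
    thresholds = attr(labels, "thresholds")
  ), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, digits = 3, ...) {
  cat("Cohort screening report\n")
  cat("=======================\n")
  if (!is.null(x$n_total_outpatients))
    cat(sprintf("Patients with a BZRA prescription: %d of %d out-patients (%.1f%%)\n",
                x$n_bzra_patients, x$n_total_outpatients,
                x$bzra_prevalence_pct))
  else
    cat("Patients with a BZRA prescription:", x$n_bzra_patients, "\n")
  cat(sprintf("Hazardous use: %d patients (%.2f%%)\n",
              x$n_hazardous, x$hazardous_prevalence_pct))
  cat(sprintf("Over-indication use: %.1f%%\n", x$over_indication_pct))
  cat("\nPer-hospital hazardous prevalence (%):\n")
  print(round(x$hazardous_by_hospital_pct, 2))
  cat("\nExposure metrics, median [IQR]:\n")
  s <- x$metric_summary
  for (m in rownames(s))
    cat(sprintf("  %-20s %.4g [%.4g-%.4g]\n", m, s[m, "median"],
                s[m, "q1"], s[m, "q3"]))
  cat("\nDrug-class use (%):\n")
  print(round(x$drug_class_use_pct, 1))
  if (nrow(x$over_indication_ranking)) {
    cat("\nTop drugs among over-indication users:\n")
    top <- utils::head(x$over_indication_ranking, 3)
    for (i in seq_len(nrow(top)))
      cat(sprintf("  %s: %.1f%% (%s)\n", top$drug_id[i],
                  top$pct_of_over_indication[i], top$top_blocks[i]))
  }
  invisible(x)
}
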
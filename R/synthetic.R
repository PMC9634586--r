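#' Configuration for the synthetic prescription-record generator
#'
#' The generator emulates a one-year, multi-hospital out-patient
#' prescription database in which most patients are short-term low-dose
#' users and small minorities follow riskier patterns. Each patient is drawn
#' from one archetype:
#' \describe{
#'   \item{casual}{1-3 non-overlapping short courses at daily doses bounded
#'     below 40 DME; never overdose, so never hazardous.}
#'   \item{long_term_stable}{contiguous refills spanning at least 100 days
#'     at sub-threshold doses; long-term but not overdose.}
#'   \item{short_overdose}{a single episode of at most 60 days dosed so the
#'     best 90-day window average exceeds 40 DME; overdose but not
#'     long-term.}
#'   \item{hazardous}{refills constructed to yield both a gap-bridged
#'     episode of at least 100 days and a 90-day window average above 40
#'     DME; the planted phenotype is guaranteed by construction.}
#'   \item{doctor_shopper}{many short low-dose dispensings from many
#'     distinct prescribers.}
#' }
#' Default proportions place 3\% of patients in the hazardous archetype and
#' set the over-indication probability to 55.9\%, the orders of magnitude
#' reported for large psychiatric out-patient populations; demographics
#' default to a two-thirds-female, mostly 18-64 cohort.
#'
#' @param n_patients number of patients.
#' @param n_hospitals number of hospitals (patients are nested: each patient
#'   attends exactly one hospital).
#' @param year study calendar year.
#' @param seed integer seed; the record stream is a deterministic function
#'   of the full config.
#' @param archetype_mix named proportions over the five archetypes, summing
#'   to 1.
#' @param over_indication_prob probability that a patient's recorded
#'   diagnoses justify none of their dispensed drugs.
#' @param gender_mix,age_mix named demographic proportions.
#' @param missing_prob probability that a patient has gender, age or
#'   diagnosis information missing (exercises the exclusion path).
#' @return a \code{cohort_config} list.
#' @export
cohort_config <- function(n_patients = 1000L, n_hospitals = 5L, year = 2018L,
                          seed = 1L,
                          archetype_mix = c(casual = 0.82,
                                            long_term_stable = 0.08,
                                            short_overdose = 0.04,
                                            hazardous = 0.03,
                                            doctor_shopper = 0.03),
                          over_indication_prob = 0.559,
                          gender_mix = c(female = 0.636, male = 0.364),
                          age_mix = c("<18" = 0.03, "18-64" = 0.762,
                                      ">=65" = 0.208),
                          missing_prob = 0.02) {
  archetypes <- c("casual", "long_term_stable", "short_overdose",
                  "hazardous", "doctor_shopper")
  mix <- archetype_mix[archetypes]
  mix[is.na(mix)] <- 0
  names(mix) <- archetypes
  if (abs(sum(mix) - 1) > 1e-9)
    stop("archetype_mix must sum to 1", call. = FALSE)
  if (any(mix < 0) || any(mix > 1))
    stop("archetype proportions must lie in [0, 1]", call. = FALSE)
  if (n_hospitals < 1L || n_patients < n_hospitals)
    stop("need n_hospitals >= 1 and n_patients >= n_hospitals",
         call. = FALSE)
  if (over_indication_prob < 0 || over_indication_prob > 1)
    stop("over_indication_prob must lie in [0, 1]", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 n_hospitals = as.integer(n_hospitals),
                 year = as.integer(year), seed = as.integer(seed),
                 archetype_mix = mix,
                 over_indication_prob = over_indication_prob,
                 gender_mix = gender_mix / sum(gender_mix),
                 age_mix = age_mix / sum(age_mix),
                 missing_prob = missing_prob),
            class = "cohort_config")
}

# drug popularity weights: clonazepam and alprazolam predominate, zaleplon /
# nitrazepam / midazolam are rare
.drug_weights <- c(clonazepam = 0.25, alprazolam = 0.20, eszopiclone = 0.12,
                   zolpidem = 0.10, estazolam = 0.08, lorazepam = 0.08,
                   diazepam = 0.06, zopiclone = 0.04, oxazepam = 0.03,
                   nitrazepam = 0.02, zaleplon = 0.01, midazolam = 0.01)

# diagnoses outside every default indication set
.off_indication_codes <- c("F32.1", "F33.2", "F20.0", "F25.1", "F99", "F10.2")

.hospital_regions <- function(n_hospitals) {
  rep(c("east", "east", "west", "central", "central"),
      length.out = n_hospitals)
}

# split a contiguous span of days into refill chunks of <= 30 days
.refill_chunks <- function(span) {
  n_full <- span %/% 30L
  rest <- span %% 30L
  c(rep(30L, n_full), if (rest > 0L) rest)
}

#' Generate a synthetic prescription cohort
#'
#' Draws a seeded synthetic prescription-record stream under a
#' [cohort_config()]. Hazardous patients are planted constructively: refill
#' dates and doses are computed to exceed both the overdose and long-term
#' thresholds, so the phenotype is guaranteed rather than sampled. All
#' planted episodes are placed to fit inside the study year. Supplies are
#' capped at 30 days, mirroring prescription length restrictions.
#'
#' @param config a \code{cohort_config}.
#' @param registry a \code{dme_registry} used to translate target DME doses
#'   into drug-specific mg doses.
#' @return data frame of prescription records (see [prescription_columns])
#'   with attributes \code{archetype} (named character vector, one entry per
#'   patient) and \code{hospitals} (data frame hospital_id/region).
#' @export
generate_cohort <- function(config, registry = load_registry()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  nd <- .year_days(config$year)
  year0 <- as.Date(sprintf("%d-01-01", config$year))

  hosp_ids <- sprintf("H%02d", seq_len(config$n_hospitals))
  hospitals <- data.frame(hospital_id = hosp_ids,
                          region = .hospital_regions(config$n_hospitals),
                          stringsAsFactors = FALSE)
  # every hospital gets at least one patient
  hosp_of <- c(hosp_ids,
               sample(hosp_ids, n - config$n_hospitals, replace = TRUE))
  archetype <- sample(names(config$archetype_mix), n, replace = TRUE,
                      prob = config$archetype_mix)
  gender <- sample(names(config$gender_mix), n, replace = TRUE,
                   prob = config$gender_mix)
  age_grp <- sample(names(config$age_mix), n, replace = TRUE,
                    prob = config$age_mix)
  age <- ifelse(age_grp == "<18", sample(10:17, n, replace = TRUE),
                ifelse(age_grp == "18-64", sample(18:64, n, replace = TRUE),
                       sample(65:90, n, replace = TRUE)))
  over_ind <- stats::runif(n) < config$over_indication_prob
  missing_kind <- ifelse(stats::runif(n) < config$missing_prob,
                         sample(c("gender", "age", "diagnoses"), n,
                                replace = TRUE), "none")

  drugs <- names(.drug_weights)
  dme_per_mg <- registry$drugs$dme_per_mg
  names(dme_per_mg) <- registry$drugs$drug_id
  n_doctors_per_hosp <- 40L

  recs <- vector("list", n)
  for (p in seq_len(n)) {
    pid <- sprintf("P%06d", p)
    hosp <- hosp_of[p]
    doctor_pool <- sprintf("%s_D%02d", hosp, seq_len(n_doctors_per_hosp))
    a <- archetype[p]

    if (a == "casual") {
      n_rx <- sample(1:3, 1)
      dose_dme <- pmin(35, stats::rlnorm(n_rx, log(8), 0.6))
      days <- sample(7:30, n_rx, replace = TRUE)
      starts <- integer(n_rx)
      starts[1] <- sample(seq_len(nd), 1)
      if (n_rx > 1) for (k in 2:n_rx)
        starts[k] <- starts[k - 1] + days[k - 1] + sample(1:45, 1)
      keep <- starts <= nd
      starts <- starts[keep]; days <- days[keep]; dose_dme <- dose_dme[keep]
      doctors <- sample(doctor_pool, length(starts), replace = TRUE)
      drug <- sample(drugs, length(starts), replace = TRUE,
                     prob = .drug_weights)
    } else if (a == "long_term_stable") {
      span <- sample(100:260, 1)
      dose_dme <- stats::runif(1, 5, 30)
      days <- .refill_chunks(span)
      starts <- sample(seq_len(nd - span + 1L), 1) +
        cumsum(c(0L, utils::head(days, -1L)))
      drug <- rep(sample(drugs, 1, prob = .drug_weights), length(days))
      dose_dme <- rep(dose_dme, length(days))
      doctors <- rep(sample(doctor_pool, 1), length(days))
    } else if (a == "short_overdose") {
      span <- sample(20:60, 1)
      dose_dme <- 40 * 90 / span * stats::runif(1, 1.15, 1.6)
      days <- .refill_chunks(span)
      starts <- sample(seq_len(nd - span + 1L), 1) +
        cumsum(c(0L, utils::head(days, -1L)))
      drug <- rep(sample(drugs, 1, prob = .drug_weights), length(days))
      dose_dme <- rep(dose_dme, length(days))
      doctors <- sample(doctor_pool, length(days), replace = TRUE)
    } else if (a == "hazardous") {
      # contiguous refills with a few bridgeable gaps; dose > 50 DME/day so
      # any 90-day window inside the episode averages above 40 even with up
      # to 9 gap days bridged
      use_span <- sample(100:280, 1)
      dose_dme <- stats::runif(1, 50, 90)
      days <- .refill_chunks(use_span)
      gaps <- c(0L, sample(0:3, length(days) - 1L, replace = TRUE,
                           prob = c(0.7, 0.1, 0.1, 0.1)))
      offsets <- cumsum(c(0L, utils::head(days, -1L))) + cumsum(gaps)
      total_span <- max(offsets + days)
      starts <- sample(seq_len(nd - total_span + 1L), 1) + offsets
      drug <- rep(sample(drugs, 1, prob = .drug_weights), length(days))
      dose_dme <- rep(dose_dme, length(days))
      doctors <- sample(doctor_pool, length(days), replace = TRUE)
    } else { # doctor_shopper
      n_rx <- sample(8:20, 1)
      dose_dme <- stats::runif(n_rx, 2, 12)
      days <- sample(3:7, n_rx, replace = TRUE)
      starts <- sort(sample(seq_len(nd), n_rx, replace = TRUE))
      doctors <- sample(doctor_pool, min(n_rx, n_doctors_per_hosp))
      doctors <- rep_len(doctors, n_rx)
      drug <- sample(drugs, n_rx, replace = TRUE, prob = .drug_weights)
    }

    dose_mg <- round(dose_dme / dme_per_mg[drug], 2)
    dose_mg <- pmax(dose_mg, 0.01)

    # pooled year diagnoses: all off-indication, or at least one match
    n_bad <- sample(1:2, 1)
    codes <- sample(.off_indication_codes, n_bad)
    if (!over_ind[p]) {
      d1 <- sample(drug, 1)
      pref <- sample(registry$indications[[d1]], 1)
      codes <- c(paste0(pref, ".0"), codes)
    }
    diag_str <- paste(codes, collapse = ";")

    m <- length(starts)
    recs[[p]] <- data.frame(
      patient_id = rep(pid, m), hospital_id = rep(hosp, m),
      doctor_id = doctors,
      visit_date = format(year0 + (starts - 1L), "%Y-%m-%d"),
      drug_id = drug, daily_dose_mg = unname(dose_mg),
      days_supplied = as.integer(days),
      diagnoses = rep(if (missing_kind[p] == "diagnoses") "" else diag_str, m),
      gender = rep(if (missing_kind[p] == "gender") "" else gender[p], m),
      age_years = rep(if (missing_kind[p] == "age") NA_integer_ else
        as.integer(age[p]), m),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  names(archetype) <- sprintf("P%06d", seq_len(n))
  # supplies never overrun the 30-day cap; overruns past Dec 31 are left in
  # place for downstream truncation
  overrun <- .day_of_year(as.Date(out$visit_date), config$year) +
    out$days_supplied - 1L > nd
  attr(out, "archetype") <- archetype
  attr(out, "hospitals") <- hospitals
  attr(out, "n_boundary_truncated") <- sum(overrun)
  out
}

#' Write / read helpers for prescription CSVs
#'
#' [write_cohort()] writes records in the documented CSV dialect (ISO-8601
#' dates, semicolon-joined diagnoses); an empty record set yields a
#' header-only file. The file round-trips losslessly through
#' [read_prescriptions()].
#'
#' @param records prescription records data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cohort <- function(records, path) {
  cols <- intersect(prescription_columns, names(records))
  stopifnot(identical(cols, prescription_columns))
  out <- records[, prescription_columns]
  if (nrow(out) && inherits(out$visit_date, "Date"))
    out$visit_date <- format(out$visit_date, "%Y-%m-%d")
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
    TRUE
  }, error = function(e)
    stop("failed writing cohort to '", path, "': ", conditionMessage(e),
         call. = FALSE))
  invisible(path)
}

#' Simulate a model-ready design for regression parameter recovery
#'
#' Draws patient covariates and a binary hazardous-use outcome from a
#' linear-probability model with a hospital random intercept, for verifying
#' that [fit_hazard_model()] recovers planted coefficients. Default planted
#' effects have the magnitudes reported for hazardous-use predictors in
#' large prescription-database studies (risk differences of 0.005-0.018 per
#' covariate unit); region effects are planted at zero.
#'
#' @param n number of patients.
#' @param n_hospitals number of hospitals.
#' @param betas named vector of planted coefficients: intercept, age_18_64,
#'   age_ge65, male, over_indication, n_visits, n_distinct_doctors.
#' @param sd_hospital standard deviation of the hospital random intercept.
#' @param seed integer seed.
#' @return data frame with outcome \code{hazardous}, the model covariates
#'   and \code{hospital_id}; planted values attached as attributes
#'   \code{betas} and \code{sd_hospital}.
#' @export
simulate_hazard_design <- function(n = 20000L, n_hospitals = 5L,
                                   betas = c(intercept = 0.05,
                                             age_18_64 = 0.018,
                                             age_ge65 = 0.015,
                                             male = 0.005,
                                             over_indication = 0.013,
                                             n_visits = 0.006,
                                             n_distinct_doctors = 0.007),
                                   sd_hospital = 0.01, seed = 1L) {
  set.seed(seed)
  hosp <- sprintf("H%02d", sample(seq_len(n_hospitals), n, replace = TRUE))
  u <- stats::rnorm(n_hospitals, 0, sd_hospital)
  names(u) <- sprintf("H%02d", seq_len(n_hospitals))
  region <- .hospital_regions(n_hospitals)
  names(region) <- names(u)

  age_group <- factor(sample(c("<18", "18-64", ">=65"), n, replace = TRUE,
                             prob = c(0.05, 0.75, 0.20)),
                      levels = c("<18", "18-64", ">=65"))
  gender <- factor(sample(c("female", "male"), n, replace = TRUE,
                          prob = c(0.64, 0.36)),
                   levels = c("female", "male"))
  over_indication <- stats::rbinom(n, 1, 0.56)
  n_visits <- 1L + stats::rpois(n, 2)
  n_doctors <- 1L + stats::rbinom(n, n_visits - 1L, 0.4)

  p <- betas["intercept"] +
    betas["age_18_64"] * (age_group == "18-64") +
    betas["age_ge65"] * (age_group == ">=65") +
    betas["male"] * (gender == "male") +
    betas["over_indication"] * over_indication +
    betas["n_visits"] * n_visits +
    betas["n_distinct_doctors"] * n_doctors +
    u[hosp]
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  d <- data.frame(
    hazardous = stats::rbinom(n, 1, p),
    age_group = age_group, gender = gender,
    region = factor(region[hosp], levels = c("east", "central", "west")),
    over_indication = over_indication,
    n_visits = n_visits, n_distinct_doctors = n_doctors,
    hospital_id = hosp, stringsAsFactors = FALSE
  )
  attr(d, "betas") <- betas
  attr(d, "sd_hospital") <- sd_hospital
  d
}
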
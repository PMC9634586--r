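#' Build the model-ready design table for the hazardous-use regression
#'
#' Joins per-patient exposure metrics, hazard labels and demographics into
#' the covariate set of the multilevel model — age group (reference <18),
#' gender (reference female), region (reference east, a hospital attribute),
#' over-indication use, annual visit count and distinct-doctor count — and
#' drops patients with any missing covariate (the soft-exclusion tier).
#' Covariates constant across the cohort are dropped with a warning to
#' protect the design's rank.
#'
#' @param metrics per-patient metrics from [compute_exposure()].
#' @param labels per-patient labels from [classify_cohort()].
#' @param hospital_regions optional data frame (hospital_id, region) mapping
#'   hospitals to regions; if absent the region covariate is omitted.
#' @return list of class \code{hazard_design}: \code{design} (data frame),
#'   \code{n_used}, \code{n_dropped_missing}, \code{dropped_covariates}.
#' @export
build_design <- function(metrics, labels, hospital_regions = NULL) {
  lab <- labels[match(metrics$patient_id, labels$patient_id), ]
  d <- data.frame(
    patient_id = metrics$patient_id,
    hazardous = as.integer(lab$hazardous),
    age_group = .age_group(metrics$age_years),
    gender = factor(metrics$gender, levels = c("female", "male")),
    over_indication = as.integer(lab$over_indication),
    n_visits = metrics$n_visits,
    n_distinct_doctors = metrics$n_distinct_doctors,
    hospital_id = metrics$hospital_id,
    stringsAsFactors = FALSE
  )
  if (!is.null(hospital_regions)) {
    d$region <- factor(
      hospital_regions$region[match(d$hospital_id,
                                    hospital_regions$hospital_id)],
      levels = c("east", "central", "west"))
  }
  covars <- setdiff(names(d), c("patient_id", "hazardous", "hospital_id"))
  complete <- stats::complete.cases(d[, covars])
  n_dropped <- sum(!complete)
  d <- d[complete, ]

  dropped <- character(0)
  for (v in covars) {
    if (length(unique(d[[v]])) < 2L) {
      warning("covariate '", v, "' is constant; dropped from the design")
      d[[v]] <- NULL
      dropped <- c(dropped, v)
    }
  }
  structure(list(design = d, n_used = nrow(d),
                 n_dropped_missing = n_dropped,
                 dropped_covariates = dropped),
            class = "hazard_design")
}

#' Fit the multilevel hazardous-use regression
#'
#' Regresses the binary hazardous-use indicator on the patient covariates
#' with a hospital random intercept, for cohorts where patients are nested
#' within hospitals. The default family is a linear probability model
#' (identity link, fitted by REML via \code{lme4::lmer}), under which
#' coefficients are risk differences per covariate unit; a logistic variant
#' (\code{lme4::glmer}, Laplace approximation) is provided. 95\% confidence
#' intervals are Wald-type from the fitted standard errors. Fitting is
#' deterministic for a given design.
#'
#' Note that when region is a hospital-level covariate and only a handful of
#' hospitals are present, the region fixed effects and the hospital random
#' intercept are weakly identified; a message flags this rather than
#' resolving it silently.
#'
#' @param design a \code{hazard_design} from [build_design()], or a plain
#'   data frame with a \code{hazardous} column, covariates, and
#'   \code{hospital_id}.
#' @param family \code{"linear_probability"} (default) or
#'   \code{"logistic"}.
#' @return object of class \code{hazard_model}: list with
#'   \code{coefficients} (data frame covariate/beta/se/ci_low/ci_high),
#'   \code{ranef_variance}, \code{family}, \code{n_used},
#'   \code{n_dropped_missing} and the underlying \code{fit}.
#' @export
fit_hazard_model <- function(design,
                             family = c("linear_probability", "logistic")) {
  family <- match.arg(family)
  if (inherits(design, "hazard_design")) {
    d <- design$design
    n_dropped <- design$n_dropped_missing
  } else {
    d <- design
    n_dropped <- 0L
  }
  stopifnot(is.data.frame(d), "hazardous" %in% names(d),
            "hospital_id" %in% names(d))
  if (length(unique(d$hospital_id)) < 2L)
    stop("only one hospital in the design: a random intercept is not ",
         "identifiable; fit a fixed-effect model instead", call. = FALSE)
  if (sum(d$hazardous) < 1L)
    stop("no hazardous-use events in the design", call. = FALSE)
  covars <- setdiff(names(d), c("patient_id", "hazardous", "hospital_id"))
  if ("region" %in% covars && length(unique(d$hospital_id)) <= 6L)
    message("region is a hospital-level covariate with few hospitals; ",
            "region effects and the hospital intercept are weakly identified")

  fm <- stats::as.formula(paste("hazardous ~",
                                paste(covars, collapse = " + "),
                                "+ (1 | hospital_id)"))
  fit <- if (family == "linear_probability") {
    lme4::lmer(fm, data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  } else {
    lme4::glmer(fm, data = d, family = stats::binomial(),
                control = lme4::glmerControl(check.conv.singular = "ignore"))
  }
  cf <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- stats::qnorm(0.975)
  coefs <- data.frame(covariate = names(cf), beta = unname(cf),
                      se = unname(se),
                      ci_low = unname(cf - z * se),
                      ci_high = unname(cf + z * se),
                      stringsAsFactors = FALSE, row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  ranef_var <- vc$vcov[vc$grp == "hospital_id"][1]
  structure(list(coefficients = coefs, ranef_variance = ranef_var,
                 family = family, n_used = nrow(d),
                 n_dropped_missing = n_dropped, fit = fit),
            class = "hazard_model")
}

#' @export
print.hazard_model <- function(x, digits = 4, ...) {
  cat("Multilevel hazardous-use regression (", x$family,
      ", hospital random intercept)\n", sep = "")
  cat("n =", x$n_used, "patients;", x$n_dropped_missing,
      "dropped for missing covariates\n\n")
  cf <- x$coefficients
  cf$beta <- signif(cf$beta, digits)
  cf$ci <- sprintf("[%s, %s]", signif(x$coefficients$ci_low, digits),
                   signif(x$coefficients$ci_high, digits))
  print(cf[, c("covariate", "beta", "ci")], row.names = FALSE)
  cat(sprintf("\nHospital intercept variance: %.3g (sd %.3g)\n",
              x$ranef_variance, sqrt(x$ranef_variance)))
  invisible(x)
}

#' @export
summary.hazard_model <- function(object, ...) {
  print(object)
  cat("\nUnderlying fit:\n")
  print(summary(object$fit))
  invisible(object)
}

#' @export
coef.hazard_model <- function(object, ...) {
  stats::setNames(object$coefficients$beta, object$coefficients$covariate)
}

#' @export
confint.hazard_model <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  cf <- object$coefficients
  m <- cbind(cf$beta - z * cf$se, cf$beta + z * cf$se)
  dimnames(m) <- list(cf$covariate,
                      sprintf("%.1f %%", c((1 - level) / 2,
                                           1 - (1 - level) / 2) * 100))
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' @export
predict.hazard_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  if (object$family == "logistic")
    stats::predict(object$fit, newdata = newdata, allow.new.levels = TRUE,
                   type = "response", ...)
  else
    stats::predict(object$fit, newdata = newdata, allow.new.levels = TRUE,
                   ...)
}
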
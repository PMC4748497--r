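#' Synthetic validation cohorts
#'
#' Generates cohorts resembling a SEER-registry validation population of men
#' with localized prostate cancer: integer ages from a truncated normal
#' calibrated to a median of 67 within the life table's 50-75 range, and
#' independent Bernoulli comorbidity draws at registry prevalences (angina
#' 13%, congestive heart failure 7.2%, diabetes 18%, heart attack 11%, high
#' blood pressure 43%, stroke 5%). Survival outcomes are then simulated from
#' the model's own predicted risks, so the prediction-validation loop can be
#' closed without any external data: a correct implementation must calibrate
#' on the identity against its own simulations.
#'
#' @name synthetic_cohort
NULL

default_prevalences <- function() {
  list(
    hypertension = 0.43,
    angina = 0.13,
    congestive_heart_failure = 0.072,
    heart_attack = 0.11,
    diabetes = 0.18,
    stroke = 0.05
  )
}

#' Specify a synthetic cohort
#'
#' @param n Number of patients.
#' @param seed Integer seed; the same spec and seed reproduce the cohort
#'   exactly.
#' @param prevalences Named list of comorbidity prevalences (proportions in
#'   \[0, 1\]). Defaults to the registry-like values above; any profile flag
#'   or the names `diabetes` / `stroke` may be given. Comorbidities not
#'   named are absent.
#' @param age_location,age_scale,age_min,age_max Truncated-normal age
#'   parameters (defaults calibrated so integer ages have median 67 within
#'   50-75).
#' @param censor_horizon Administrative censoring time in years (default 18,
#'   so both the 10- and 15-year endpoints are observable).
#' @param stroke_infarction_share Among stroke cases, the fraction assigned
#'   infarction/thrombosis/embolism rather than hemorrhage (default 0.8).
#' @param diabetes_band Duration band assigned to diabetic patients
#'   (default `"0-5"`).
#' @param correlation Optional function `(patients) -> patients` applied
#'   after the independent draws, a hook for inducing comorbidity
#'   correlation; the default `NULL` keeps draws independent.
#' @return A list of class `ocm_cohort_spec`.
#' @export
cohort_spec <- function(n, seed = 1L, prevalences = default_prevalences(),
                        age_location = 77.56616, age_scale = 13,
                        age_min = 50, age_max = 75,
                        censor_horizon = 18,
                        stroke_infarction_share = 0.8,
                        diabetes_band = "0-5",
                        correlation = NULL) {
  if (length(n) != 1 || is.na(n) || n < 1) stop_input("n must be a positive count")
  bad <- names(prevalences)[!vapply(prevalences, function(p)
    is.numeric(p) && !is.na(p) && p >= 0 && p <= 1, logical(1))]
  if (length(bad) > 0) {
    stop_input(sprintf("prevalence(s) outside [0, 1]: %s", paste(bad, collapse = ", ")))
  }
  allowed <- c(setdiff(profile_flag_fields, c("high_total_cholesterol", "low_hdl")),
               "diabetes", "stroke", "smoking_current", "smoking_former",
               "high_total_cholesterol", "low_hdl",
               "asthma_mild", "asthma_moderate", "asthma_severe")
  unknown <- setdiff(names(prevalences), allowed)
  if (length(unknown) > 0) {
    stop_input(sprintf("unknown prevalence name(s): %s", paste(unknown, collapse = ", ")))
  }
  if (!diabetes_band %in% setdiff(profile_categorical_levels$diabetes, "none")) {
    stop_input("diabetes_band must be one of: 0-5, 6-10, 11-20, >20")
  }
  structure(list(
    n = as.integer(n), seed = as.integer(seed), prevalences = prevalences,
    age_location = age_location, age_scale = age_scale,
    age_min = age_min, age_max = age_max,
    censor_horizon = censor_horizon,
    stroke_infarction_share = stroke_infarction_share,
    diabetes_band = diabetes_band,
    correlation = correlation
  ), class = "ocm_cohort_spec")
}

# inverse-CDF draw from a normal truncated to [age_min, age_max]
rtruncnorm_age <- function(n, mu, sigma, lo, hi) {
  plo <- stats::pnorm((lo - mu) / sigma)
  phi <- stats::pnorm((hi - mu) / sigma)
  mu + sigma * qnorm(plo + runif(n) * (phi - plo))
}

#' Generate a synthetic patient cohort
#'
#' @param spec A [cohort_spec()].
#' @return A validated patient tibble of `spec$n` rows (ages floored to
#'   completed years, all profile columns present). Byte-identical for
#'   identical specs.
#' @examples
#' generate_cohort(cohort_spec(5, seed = 42))
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "ocm_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n
  age <- floor(rtruncnorm_age(n, spec$age_location, spec$age_scale,
                              spec$age_min, spec$age_max))
  age <- pmin(age, spec$age_max) # guard the half-open upper cell
  patients <- tibble(age = as.numeric(age))
  prev <- spec$prevalences
  draw <- function(p) runif(n) < p
  for (f in setdiff(profile_flag_fields, c("high_total_cholesterol", "low_hdl"))) {
    patients[[f]] <- if (!is.null(prev[[f]])) draw(prev[[f]]) else rep(FALSE, n)
  }
  for (f in c("high_total_cholesterol", "low_hdl")) {
    patients[[f]] <- if (!is.null(prev[[f]])) draw(prev[[f]]) else rep(FALSE, n)
  }
  patients$diabetes <- rep("none", n)
  if (!is.null(prev$diabetes)) {
    patients$diabetes[draw(prev$diabetes)] <- spec$diabetes_band
  }
  patients$stroke <- rep("none", n)
  if (!is.null(prev$stroke)) {
    has_stroke <- draw(prev$stroke)
    subtype <- ifelse(runif(n) < spec$stroke_infarction_share, "infarction", "hemorrhage")
    patients$stroke[has_stroke] <- subtype[has_stroke]
  }
  patients$smoking <- rep("never", n)
  p_cur <- prev$smoking_current %||% 0
  p_for <- prev$smoking_former %||% 0
  if (p_cur + p_for > 1) stop_input("smoking prevalences sum to more than 1")
  if (p_cur + p_for > 0) {
    u <- runif(n)
    patients$smoking[u < p_cur] <- "current"
    patients$smoking[u >= p_cur & u < p_cur + p_for] <- "former"
  }
  patients$asthma <- rep("none", n)
  for (lev in c("mild", "moderate", "severe")) {
    p <- prev[[paste0("asthma_", lev)]]
    if (!is.null(p)) patients$asthma[patients$asthma == "none" & draw(p)] <- lev
  }
  if (!is.null(spec$correlation)) patients <- spec$correlation(patients)
  validate_patients(patients)
}

#' Simulate censored survival outcomes from the model's own predictions
#'
#' Each patient's event time is drawn from a two-piece exponential whose
#' cumulative event probability equals the model-predicted 10-year risk at 10
#' years and the 15-year risk at 15 years exactly (the second piece's hazard
#' continues beyond 15 years). Administrative censoring is applied at
#' `censor_horizon`. The output feeds [validate_cohort()] directly, and by
#' construction a correct implementation calibrates on the identity.
#'
#' @param cohort A patient tibble (e.g. from [generate_cohort()]), or one
#'   already carrying `adjusted_risk_10y` / `adjusted_risk_15y` columns.
#' @param model An [ocm_model()]; built with defaults when `NULL`.
#' @param seed Integer seed for the event-time draws.
#' @param censor_horizon Administrative censoring time in years.
#' @return The cohort tibble with `predicted_risk_10y`, `predicted_risk_15y`,
#'   `followup_years` and `event` appended.
#' @export
simulate_outcomes <- function(cohort, model = NULL, seed = 1L, censor_horizon = 18) {
  if (length(censor_horizon) != 1 || is.na(censor_horizon) || censor_horizon < 0) {
    stop_input("censor_horizon must be a non-negative number of years")
  }
  need <- c("adjusted_risk_10y", "adjusted_risk_15y")
  if (!all(need %in% names(cohort))) {
    cohort <- predict_ocm(cohort, model = model, horizons = c(10, 15))
  }
  p10 <- cohort$adjusted_risk_10y
  p15 <- cohort$adjusted_risk_15y
  if (any(p15 < p10)) {
    stop_input("predicted 15-year risk below 10-year risk: inconsistent model tables")
  }
  set.seed(seed)
  n <- nrow(cohort)
  # piecewise-constant hazard solved from the two cumulative probabilities
  lam1 <- -log(1 - p10) / 10
  lam2 <- (log(1 - p10) - log(1 - p15)) / 5
  e <- rexp(n)
  t_event <- ifelse(
    e < 10 * lam1,
    e / lam1,
    10 + (e - 10 * lam1) / ifelse(lam2 > 0, lam2, NA_real_)
  )
  t_event[lam1 == 0 & lam2 > 0] <- 10 + e[lam1 == 0 & lam2 > 0] / lam2[lam1 == 0 & lam2 > 0]
  t_event[is.na(t_event)] <- Inf # zero hazard on both pieces: never dies
  out <- cohort
  out$predicted_risk_10y <- p10
  out$predicted_risk_15y <- p15
  out$event <- t_event <= censor_horizon
  out$followup_years <- pmin(t_event, censor_horizon)
  out
}
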
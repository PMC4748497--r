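#' Assemble the model's reference tables
#'
#' Bundles the life tables (10- and 15-year baselines) and the comorbidity
#' odds-ratio table used by the prediction functions. With the default
#' `shift_years = 3` the packaged adjusted life-table columns are used
#' verbatim (ages 50-75). Any other shift rebuilds the baseline by shifting
#' the raw SSA column, which then only supports ages from
#' `50 + shift_years` upward, since risks below the printed range are never
#' invented.
#'
#' @param life_table_path Optional path to a life-table CSV (see
#'   [load_life_table()] for the layout); default is the packaged table.
#' @param or_path Optional path to an odds-ratio CSV; default packaged.
#' @param shift_years Healthier-than-average age shift in whole years
#'   (default 3).
#' @return An object of class `ocm_model`: a list with `life_tables` (named
#'   `"10"`, `"15"`), `or_table` and `shift_years`.
#' @examples
#' m <- ocm_model()
#' baseline_risk(m$life_tables[["10"]], 65) # 0.18
#' @export
ocm_model <- function(life_table_path = NULL, or_path = NULL, shift_years = 3) {
  lts <- lapply(c(`10` = 10, `15` = 15), function(h) {
    if (identical(as.numeric(shift_years), 3)) {
      load_life_table(life_table_path, horizon = h, column = "adjusted")
    } else {
      shift_life_table(load_life_table(life_table_path, horizon = h, column = "raw"),
                       shift_years)
    }
  })
  structure(
    list(life_tables = lts, or_table = load_odds_ratio_table(or_path),
         shift_years = shift_years),
    class = "ocm_model"
  )
}

#' Combined odds ratio for a patient's comorbidity profile
#'
#' Each comorbidity present in the profile contributes its tabulated odds
#' ratio (resolved through the patient's cholesterol modifier state for the
#' cholesterol-sensitive comorbidities), and the contributions are multiplied
#' together. An empty profile yields 1. The product is not capped: extreme
#' products overestimate risk only where the distinction no longer changes
#' clinical decisions.
#'
#' @param patients A validated patient data frame (one row per patient).
#' @param or_table Odds-ratio table; default packaged.
#' @param horizon 10 or 15.
#' @return Numeric vector of combined odds ratios, one per patient.
#' @examples
#' p <- ocm_profile(65, smoking = "current", angina = TRUE)
#' combined_odds_ratio(p, horizon = 10) # 2.0 * 1.55 = 3.1
#' @export
combined_odds_ratio <- function(patients, or_table = NULL, horizon = 10) {
  contrib <- odds_ratio_factors(patients, or_table, horizon)
  out <- rep(1, nrow(patients))
  if (nrow(contrib) > 0) {
    prod_by <- contrib %>%
      group_by(.data$patient) %>%
      summarise(or = prod(.data$odds_ratio), .groups = "drop")
    out[prod_by$patient] <- prod_by$or
  }
  out
}

#' Per-comorbidity odds-ratio contributions
#'
#' The audit trail behind [combined_odds_ratio()]: one row per (patient,
#' contributing comorbidity) with the applied odds ratio, after resolving
#' attribute levels and cholesterol modifiers. Comorbidities whose tabulated
#' ratio is exactly 1 (pulmonary embolus without cholesterol modifiers,
#' diabetes of 0-5 years) appear with `odds_ratio = 1`, a recorded no-op.
#'
#' @inheritParams combined_odds_ratio
#' @return Tibble with columns `patient`, `comorbidity`, `level`,
#'   `cholesterol`, `odds_ratio`.
#' @export
odds_ratio_factors <- function(patients, or_table = NULL, horizon = 10) {
  patients <- validate_patients(patients)
  or_table <- or_table %||% load_odds_ratio_table()
  stopifnot(inherits(or_table, "ocm_or_table"))
  if (!horizon %in% unique(or_table$horizon)) {
    stop_input(sprintf("horizon %s not present in the odds-ratio table", horizon))
  }
  factors <- active_factors(patients)
  if (nrow(factors) == 0) {
    return(tibble(patient = integer(0), comorbidity = character(0),
                  level = character(0), cholesterol = character(0),
                  odds_ratio = numeric(0)))
  }
  chol <- cholesterol_state(patients)
  modified <- chol_modified_comorbidities(or_table)
  factors <- factors %>%
    mutate(cholesterol = ifelse(.data$comorbidity %in% modified,
                                chol[.data$patient], "none"))
  tab <- or_table %>%
    filter(.data$horizon == !!horizon) %>%
    select("comorbidity", "level", "cholesterol", "odds_ratio")
  joined <- left_join(factors, tab, by = c("comorbidity", "level", "cholesterol"))
  if (any(is.na(joined$odds_ratio))) {
    miss <- joined[is.na(joined$odds_ratio), ]
    stop_input(sprintf(
      "no odds ratio tabulated for: %s",
      paste(unique(sprintf("%s/%s/%s", miss$comorbidity, miss$level, miss$cholesterol)),
            collapse = "; ")
    ), class = "ocm_error_lookup")
  }
  arrange(joined, .data$patient, .data$comorbidity)
}

#' Comorbidity-adjusted risk of other-cause death
#'
#' Converts the age-specific baseline risk to odds, multiplies by the
#' patient's combined comorbidity odds ratio, and converts back to a
#' probability. With an empty profile the result equals the baseline exactly;
#' the result is always in \[0, 1) for a finite odds-ratio product.
#'
#' @param baseline Baseline probability of other-cause death at the horizon
#'   (from [baseline_risk()]); must be < 1.
#' @param patients A one-row validated patient data frame (e.g. from
#'   [ocm_profile()]).
#' @param or_table Odds-ratio table; default packaged.
#' @param horizon 10 or 15.
#' @return An object of class `ocm_risk_estimate` with fields `horizon`,
#'   `baseline_risk`, `combined_odds_ratio`, `adjusted_risk` and
#'   `contributing_factors` (a tibble). `tidy()` returns the factors,
#'   `glance()` the scalar fields.
#' @examples
#' est <- adjusted_risk(0.18, ocm_profile(65, smoking = "current"), horizon = 10)
#' est$adjusted_risk        # 0.3051
#' percent_round(est$adjusted_risk) # 31
#' @export
adjusted_risk <- function(baseline, patients, or_table = NULL, horizon = 10) {
  if (length(baseline) != 1 || is.na(baseline) || baseline < 0 || baseline >= 1) {
    stop_input("baseline must be a single probability in [0, 1)")
  }
  patients <- validate_patients(patients)
  if (nrow(patients) != 1) {
    stop_input("adjusted_risk() takes a single patient; use predict_ocm() for cohorts")
  }
  contrib <- odds_ratio_factors(patients, or_table, horizon)
  or <- if (nrow(contrib) == 0) 1 else prod(contrib$odds_ratio)
  adj <- if (baseline == 0 && or >= 0) 0 else odds_to_risk(risk_to_odds(baseline) * or)
  structure(
    list(horizon = horizon, baseline_risk = baseline, combined_odds_ratio = or,
         adjusted_risk = adj,
         contributing_factors = select(contrib, -"patient")),
    class = "ocm_risk_estimate"
  )
}

#' @export
print.ocm_risk_estimate <- function(x, ...) {
  cat(sprintf("<%d-year other-cause mortality estimate>\n", x$horizon))
  cat(sprintf("  baseline risk:       %.4f (%d%%)\n", x$baseline_risk,
              percent_round(x$baseline_risk)))
  cat(sprintf("  combined odds ratio: %.4f\n", x$combined_odds_ratio))
  cat(sprintf("  adjusted risk:       %.4f (%d%%)\n", x$adjusted_risk,
              percent_round(x$adjusted_risk)))
  if (nrow(x$contributing_factors) > 0) {
    cat("  factors:\n")
    apply(x$contributing_factors, 1, function(r) {
      cat(sprintf("    %s (%s%s): OR %s\n", r[["comorbidity"]], r[["level"]],
                  if (r[["cholesterol"]] != "none") paste0(", chol ", r[["cholesterol"]]) else "",
                  r[["odds_ratio"]]))
    })
  } else {
    cat("  no comorbidities: adjusted equals baseline\n")
  }
  invisible(x)
}

#' Predict other-cause mortality for a cohort
#'
#' Data-frame-in, tibble-out: appends, for each requested horizon, the
#' baseline risk (from the age-shifted life table), the combined comorbidity
#' odds ratio and the adjusted risk.
#'
#' @param patients Patient data frame (see [comorbidity_profiles]).
#' @param model An [ocm_model()]; built with defaults when `NULL`.
#' @param horizons Numeric subset of `c(10, 15)`.
#' @return The input tibble with columns `baseline_risk_<h>y`,
#'   `odds_ratio_<h>y`, `adjusted_risk_<h>y` appended per horizon.
#' @examples
#' predict_ocm(ocm_profile(65, angina = TRUE, smoking = "current"))
#' @export
predict_ocm <- function(patients, model = NULL, horizons = c(10, 15)) {
  patients <- validate_patients(patients)
  model <- model %||% ocm_model()
  stopifnot(inherits(model, "ocm_model"))
  if (!all(horizons %in% c(10, 15))) stop_input("horizons must be a subset of c(10, 15)")
  out <- patients
  for (h in horizons) {
    lt <- model$life_tables[[as.character(h)]]
    base <- baseline_risk(lt, patients$age)
    or <- combined_odds_ratio(patients, model$or_table, horizon = h)
    out[[sprintf("baseline_risk_%dy", h)]] <- base
    out[[sprintf("odds_ratio_%dy", h)]] <- or
    out[[sprintf("adjusted_risk_%dy", h)]] <- odds_to_risk(risk_to_odds(base) * or)
  }
  out
}
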
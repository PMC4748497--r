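#' Validation of risk predictions against censored follow-up
#'
#' A validation cohort is a data frame with one row per patient carrying a
#' predicted event probability at a stated horizon (`predicted_risk`),
#' follow-up in years (`followup_years`) and an event indicator (`event`,
#' logical or 0/1: other-cause death vs. censored). Prostate-cancer deaths
#' should be recoded with [recode_events()] before validation; by default
#' they censor the other-cause endpoint (cause-specific convention).
#'
#' @name validation
NULL

#' Recode a 0/1/2 event code for other-cause validation
#'
#' @param event_code Integer vector: 0 censored, 1 other-cause death,
#'   2 prostate-cancer death.
#' @param pc_deaths `"censor"` (default, cause-specific other-cause endpoint)
#'   or `"event"` (all-cause endpoint).
#' @return Logical event indicator.
#' @export
recode_events <- function(event_code, pc_deaths = c("censor", "event")) {
  pc_deaths <- match.arg(pc_deaths)
  if (!all(event_code %in% c(0, 1, 2))) {
    stop_input("event_code must contain only 0 (censored), 1 (other-cause death), 2 (prostate-cancer death)")
  }
  if (pc_deaths == "censor") event_code == 1 else event_code %in% c(1, 2)
}

check_cohort <- function(data, risk, time, event) {
  if (!is.data.frame(data)) stop_input("data must be a data frame")
  for (col in c(risk, time, event)) {
    if (!col %in% names(data)) stop_input(sprintf("missing cohort column '%s'", col))
  }
  r <- data[[risk]]; t <- data[[time]]; e <- data[[event]]
  if (is.numeric(e) && all(e %in% c(0, 1))) e <- e == 1
  if (!is.logical(e) || any(is.na(e))) stop_input("event must be logical or 0/1")
  if (any(is.na(t)) || any(t < 0)) stop_input("followup times must be non-negative")
  if (any(is.na(r)) || any(r < 0 | r > 1)) stop_input("predicted risks must lie in [0, 1]")
  list(risk = as.numeric(r), time = as.numeric(t), event = e)
}

#' Harrell's concordance index
#'
#' The probability, over usable pairs under censoring, that the patient with
#' the higher predicted risk dies earlier. A pair is usable only when the
#' member with strictly shorter follow-up had an event (pairs with tied
#' follow-up times are unusable); tied predictions on usable pairs count 1/2.
#' 0.5 is chance, 1 perfect discrimination.
#'
#' @param data Cohort data frame.
#' @param risk,time,event Column names (defaults `"predicted_risk"`,
#'   `"followup_years"`, `"event"`).
#' @return A single concordance value in \[0, 1\].
#' @examples
#' d <- data.frame(predicted_risk = c(.9, .5, .1),
#'                 followup_years = c(1, 2, 3), event = c(1, 1, 1))
#' harrells_c(d) # 1
#' @export
harrells_c <- function(data, risk = "predicted_risk", time = "followup_years",
                       event = "event") {
  v <- check_cohort(data, risk, time, event)
  if (length(v$time) < 2) stop_input("concordance needs at least 2 records")
  if (!any(v$event)) stop_input("concordance needs at least one event", class = "ocm_error_concordance")
  cnt <- concordance_counts(v$time, v$event, v$risk)
  if (cnt[["usable"]] == 0) {
    stop_input("no usable pairs: concordance is undefined", class = "ocm_error_concordance")
  }
  unname(cnt[["concordant"]] / cnt[["usable"]])
}

#' Kaplan-Meier event probability at a horizon
#'
#' One minus the product-limit survival estimate at `horizon`. With no
#' censoring before the horizon this equals the empirical proportion of
#' events by the horizon.
#'
#' @param times Non-negative follow-up times in years.
#' @param events Event indicators (logical or 0/1).
#' @param horizon Years.
#' @return A probability, or `NA` with a warning when no subject's follow-up
#'   reaches past the observed events (estimate undefined).
#' @examples
#' km_event_probability(c(2, 4, 6, 8, 12), c(1, 1, 0, 1, 0), 10) # 0.7
#' @export
km_event_probability <- function(times, events, horizon) {
  if (length(times) == 0) stop_input("no subjects: Kaplan-Meier estimate undefined")
  if (any(is.na(times)) || any(times < 0)) stop_input("times must be non-negative")
  if (is.numeric(events)) events <- events == 1
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  s <- summary(fit, times = horizon, extend = TRUE)$surv
  if (length(s) != 1 || is.na(s)) {
    warn("Kaplan-Meier estimate undefined at the requested horizon",
         class = "ocm_warning_km_undefined")
    return(NA_real_)
  }
  1 - s
}

#' Horizon-specific calibration curve
#'
#' Partitions the cohort into quantile bins of predicted risk (ties assigned
#' to the lower bin) and compares, per bin, the mean predicted risk with the
#' observed Kaplan-Meier event probability at the horizon. A well-calibrated
#' model lies on the identity line.
#'
#' @inheritParams harrells_c
#' @param horizon Years at which predictions were made.
#' @param n_bins Number of quantile bins (default 10; at least 2). Tied
#'   prediction values can merge adjacent bins, so fewer bins may be
#'   returned.
#' @return A tibble of class `ocm_calibration` with columns `bin`, `n`,
#'   `events`, `mean_predicted`, `observed`; attribute `horizon`. Bins where
#'   the Kaplan-Meier estimate is undefined carry `observed = NA` and are
#'   flagged with a warning.
#' @export
calibration_curve <- function(data, horizon, n_bins = 10,
                              risk = "predicted_risk", time = "followup_years",
                              event = "event") {
  v <- check_cohort(data, risk, time, event)
  if (n_bins < 2) stop_input("n_bins must be at least 2")
  breaks <- unique(quantile(v$risk, probs = seq(0, 1, length.out = n_bins + 1),
                            type = 7, names = FALSE))
  if (length(breaks) < 2) {
    bin <- rep(1L, length(v$risk)) # constant predictions: one effective bin
  } else {
    bin <- cut(v$risk, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  }
  df <- tibble(bin = bin, risk = v$risk, time = v$time, event = v$event)
  out <- df %>%
    group_by(.data$bin) %>%
    summarise(
      n = dplyr::n(),
      events = sum(.data$event),
      mean_predicted = mean(.data$risk),
      observed = km_event_probability(.data$time, .data$event, horizon),
      .groups = "drop"
    ) %>%
    arrange(.data$mean_predicted) %>%
    mutate(bin = row_number())
  attr(out, "horizon") <- horizon
  attr(out, "n_total") <- length(v$risk)
  class(out) <- c("ocm_calibration", class(out))
  out
}

#' Validate a cohort: discrimination and calibration together
#'
#' @inheritParams calibration_curve
#' @param horizons Horizons (years) at which to calibrate; the matching
#'   prediction column per horizon is `predicted_risk_<h>y` if present,
#'   otherwise the single `risk` column is used for all horizons.
#' @return An object of class `ocm_validation`: list with `summary` (tibble
#'   of horizon, n, events, c_index) and `calibration` (named list of
#'   [calibration_curve()] results). Supports `tidy()`, `glance()` and
#'   `autoplot()`.
#' @export
validate_cohort <- function(data, horizons = c(10, 15), n_bins = 10,
                            risk = "predicted_risk", time = "followup_years",
                            event = "event") {
  cal <- list()
  rows <- list()
  for (h in horizons) {
    rcol <- sprintf("predicted_risk_%dy", h)
    if (!rcol %in% names(data)) rcol <- risk
    v <- check_cohort(data, rcol, time, event)
    rows[[as.character(h)]] <- tibble(
      horizon = h, n = length(v$time), events = sum(v$event),
      c_index = harrells_c(data, risk = rcol, time = time, event = event)
    )
    cal[[as.character(h)]] <- calibration_curve(data, h, n_bins, risk = rcol,
                                                time = time, event = event)
  }
  structure(list(summary = bind_rows(rows), calibration = cal),
            class = "ocm_validation")
}

#' @export
print.ocm_validation <- function(x, ...) {
  cat("<cohort validation>\n")
  print(x$summary)
  invisible(x)
}
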
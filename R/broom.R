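# broom-style verbs and ggplot2 autoplot methods for the result objects

#' @method tidy ocm_risk_estimate
#' @export
tidy.ocm_risk_estimate <- function(x, ...) {
  x$contributing_factors
}

#' @method glance ocm_risk_estimate
#' @export
glance.ocm_risk_estimate <- function(x, ...) {
  tibble(horizon = x$horizon, baseline_risk = x$baseline_risk,
         combined_odds_ratio = x$combined_odds_ratio,
         adjusted_risk = x$adjusted_risk,
         n_factors = nrow(x$contributing_factors))
}

#' @method tidy ocm_calibration
#' @export
tidy.ocm_calibration <- function(x, ...) {
  out <- as_tibble(x)
  out$horizon <- attr(x, "horizon")
  out
}

#' @method tidy ocm_validation
#' @export
tidy.ocm_validation <- function(x, ...) {
  bind_rows(lapply(x$calibration, tidy))
}

#' @method glance ocm_validation
#' @export
glance.ocm_validation <- function(x, ...) {
  x$summary
}

#' @method tidy ocm_report
#' @export
tidy.ocm_report <- function(x, ...) {
  rows <- lapply(x$estimates, function(est) glance(est))
  out <- bind_rows(rows)
  if (!is.null(x$prostate_cancer)) {
    pc <- x$prostate_cancer
    out$risk_group <- pc$risk_group
    out$untreated_pc_risk <- ifelse(out$horizon == pc$horizon, pc$untreated_pc_risk, NA_real_)
    out$conditional_pc_risk <- ifelse(out$horizon == pc$horizon, pc$conditional_pc_risk, NA_real_)
  }
  out
}

#' Calibration plot
#'
#' Mean predicted risk against observed Kaplan-Meier event probability per
#' quantile bin, with the identity line; well-calibrated predictions lie on
#' the diagonal.
#'
#' @param object An `ocm_calibration` or `ocm_validation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ocm_calibration
#' @export
autoplot.ocm_calibration <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_predicted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::geom_line() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Mean predicted risk", y = "Observed event probability (Kaplan-Meier)",
      title = sprintf("%s-year calibration", attr(object, "horizon")),
      size = "Patients"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ocm_calibration
#' @method autoplot ocm_validation
#' @export
autoplot.ocm_validation <- function(object, ...) {
  df <- tidy(object)
  df$horizon <- factor(sprintf("%d-year", df$horizon))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_predicted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~horizon) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Mean predicted risk",
                  y = "Observed event probability (Kaplan-Meier)",
                  size = "Patients") +
    ggplot2::theme_minimal()
}
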
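# Independent oracles and fixture builders shared across tests.

# Exhaustive pair-enumeration concordance: the reference the fast
# implementation must match exactly. Deliberately naive.
oracle_concordance <- function(time, event, pred) {
  pairs <- utils::combn(length(time), 2)
  num <- 0
  usable <- 0
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    if (time[i] == time[j]) next            # tied follow-up: unusable
    if (time[j] < time[i]) { tmp <- i; i <- j; j <- tmp }
    if (!event[i]) next                     # shorter follow-up must be an event
    usable <- usable + 1
    if (pred[i] > pred[j]) num <- num + 1
    else if (pred[i] == pred[j]) num <- num + 0.5
  }
  if (usable == 0) return(NA_real_)
  num / usable
}

# Random censored cohort for concordance property tests.
random_cohort <- function(n, censor_frac = 0.3, tie_preds = FALSE) {
  pred <- if (tie_preds) sample(c(.1, .3, .5, .7), n, replace = TRUE) else runif(n)
  data.frame(
    predicted_risk = pred,
    followup_years = round(rexp(n, rate = 0.1), 2),
    event = runif(n) > censor_frac
  )
}

# Write a life-table CSV (percent risks) to a temp file.
write_life_table_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  readr::write_csv(df, path)
  path
}

# In-memory copy of the packaged life-table file for perturbation tests.
packaged_life_table_df <- function() {
  readr::read_csv(system.file("extdata", "ssa_life_table.csv", package = "ocmrisk"),
                  col_types = readr::cols(.default = readr::col_double()))
}

# Random untreated-mortality table (low <= intermediate <= high) whose low
# group stays deconvolvable for upgrade fractions up to 0.6: the mixture
# identity needs low_old >= f * (low_old + int_old) / 2.
random_untreated_table <- function(n_bands = 3) {
  bands <- c("<65", "65-74", "75+")[seq_len(n_bands)]
  low <- runif(n_bands, 0.02, 0.2)
  mid <- low * runif(n_bands, 1, 1.5)
  high <- mid + runif(n_bands, 0, 0.3)
  tab <- tibble::tibble(
    risk_group = rep(c("low", "intermediate", "high"), each = n_bands),
    age_band = rep(bands, 3),
    horizon = 15,
    risk = c(low, mid, high)
  )
  ocmrisk:::validate_untreated_table(tab)
}
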
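#' Convert between risk and odds
#'
#' The comorbidity adjustment works on the odds scale: a risk r becomes odds
#' r/(1 - r), the combined odds ratio multiplies the odds, and the result
#' maps back through o/(1 + o). For example a 10-year risk of 18% is odds
#' 18:82; doubling the odds (current smoker) gives 36:82, a risk of
#' 36 / (36 + 82) = 31%.
#'
#' @param r Probability vector, each in \[0, 1); a risk of exactly 1 has
#'   undefined odds and raises an error.
#' @param o Non-negative odds vector.
#' @return `risk_to_odds()`: odds; `odds_to_risk()`: probabilities. The two
#'   are exact inverses on (0, 1).
#' @examples
#' risk_to_odds(0.18) # 18/82
#' odds_to_risk(risk_to_odds(0.18) * 2) # 0.3051
#' @export
risk_to_odds <- function(r) {
  stopifnot(is.numeric(r))
  if (any(is.na(r)) || any(r < 0) || any(r > 1)) {
    stop_input("risk must lie in [0, 1]")
  }
  if (any(r == 1)) {
    stop_input("risk of exactly 1 has undefined (infinite) odds", class = "ocm_error_odds")
  }
  r / (1 - r)
}

#' @rdname risk_to_odds
#' @export
odds_to_risk <- function(o) {
  stopifnot(is.numeric(o))
  if (any(is.na(o)) || any(o < 0)) {
    stop_input("odds must be non-negative")
  }
  o / (1 + o)
}

#' Load the comorbidity odds-ratio table
#'
#' The table maps (comorbidity, attribute level, cholesterol modifier state,
#' horizon) to a multiplicative odds ratio. Cholesterol states are `none`,
#' `high_total` (total cholesterol > 270 mg/dL), `low_hdl` (HDL < 20 mg/dL)
#' and `both`; only some comorbidities (angina, heart attack, aortic stenosis,
#' peripheral vascular disease, deep venous thrombosis, pulmonary embolus)
#' carry cholesterol-modified variants, and cholesterol never contributes a
#' standalone odds ratio. On load two invariants are asserted: every odds
#' ratio is at least 1, and within each cholesterol-modified comorbidity the
#' ratios are monotone none <= high_total <= low_hdl <= both at each horizon.
#'
#' @param path Path to the CSV file (columns `comorbidity`, `level`,
#'   `cholesterol`, `horizon`, `odds_ratio`). Defaults to the packaged table.
#' @return A tibble of class `ocm_or_table`.
#' @export
load_odds_ratio_table <- function(path = NULL) {
  path <- path %||% ocm_extdata("comorbidity_odds_ratios.csv")
  tab <- readr::read_csv(path, col_types = readr::cols(
    comorbidity = readr::col_character(),
    level = readr::col_character(),
    cholesterol = readr::col_character(),
    horizon = readr::col_double(),
    odds_ratio = readr::col_double()
  ))
  bad_chol <- setdiff(unique(tab$cholesterol), c("none", "high_total", "low_hdl", "both"))
  if (length(bad_chol) > 0) {
    stop_input(sprintf("unknown cholesterol state(s): %s", paste(bad_chol, collapse = ", ")))
  }
  if (!all(tab$horizon %in% c(10, 15))) {
    stop_input("odds-ratio table horizons must be 10 or 15 years")
  }
  if (any(is.na(tab$odds_ratio)) || any(tab$odds_ratio < 1)) {
    stop_input("all odds ratios must be >= 1.00", class = "ocm_error_or_table")
  }
  key <- paste(tab$comorbidity, tab$level, tab$cholesterol, tab$horizon)
  if (anyDuplicated(key)) {
    stop_input("duplicated (comorbidity, level, cholesterol, horizon) entries")
  }
  chol_order <- c(none = 1, high_total = 2, low_hdl = 3, both = 4)
  check <- tab %>%
    mutate(rank = chol_order[.data$cholesterol]) %>%
    arrange(.data$comorbidity, .data$level, .data$horizon, .data$rank) %>%
    group_by(.data$comorbidity, .data$level, .data$horizon) %>%
    summarise(mono = !is.unsorted(.data$odds_ratio), .groups = "drop")
  if (!all(check$mono)) {
    bad <- check[!check$mono, ]
    stop_input(sprintf(
      "cholesterol-modified odds ratios not monotone for: %s",
      paste(unique(bad$comorbidity), collapse = ", ")
    ), class = "ocm_error_or_table")
  }
  class(tab) <- c("ocm_or_table", class(tab))
  tab
}

# comorbidities that have cholesterol-modified rows in a given table
chol_modified_comorbidities <- function(or_table) {
  unique(or_table$comorbidity[or_table$cholesterol != "none"])
}

#' Look up a single odds ratio
#'
#' Resolves one comorbidity (with its attribute level and the patient's
#' cholesterol state) to its odds ratio at a horizon. Comorbidities without
#' cholesterol-modified variants ignore the cholesterol state.
#'
#' @param or_table An odds-ratio table from [load_odds_ratio_table()].
#' @param comorbidity Comorbidity name, e.g. `"congestive_heart_failure"`.
#' @param level Attribute level; `"present"` for plain flags, or e.g.
#'   `"severe"` (asthma), `"6-10"` (diabetes years), `"infarction"` (stroke),
#'   `"current"` (smoking).
#' @param cholesterol One of `"none"`, `"high_total"`, `"low_hdl"`, `"both"`.
#' @param horizon 10 or 15.
#' @return A single positive odds ratio.
#' @examples
#' ors <- load_odds_ratio_table()
#' lookup_odds_ratio(ors, "congestive_heart_failure", horizon = 10) # 3.82
#' lookup_odds_ratio(ors, "angina", cholesterol = "both", horizon = 15) # 4.09
#' @export
lookup_odds_ratio <- function(or_table, comorbidity, level = "present",
                              cholesterol = "none", horizon = 10) {
  stopifnot(inherits(or_table, "ocm_or_table"))
  if (!comorbidity %in% or_table$comorbidity) {
    stop_input(sprintf("unknown comorbidity '%s'; valid: %s", comorbidity,
                       paste(sort(unique(or_table$comorbidity)), collapse = ", ")),
               class = "ocm_error_lookup")
  }
  if (!comorbidity %in% chol_modified_comorbidities(or_table)) cholesterol <- "none"
  hit <- or_table$odds_ratio[
    or_table$comorbidity == comorbidity &
      or_table$level == level &
      or_table$cholesterol == cholesterol &
      or_table$horizon == horizon
  ]
  if (length(hit) != 1) {
    valid <- or_table[or_table$comorbidity == comorbidity, ]
    stop_input(sprintf(
      "no odds ratio for %s (level '%s', cholesterol '%s', %s years); valid levels: %s",
      comorbidity, level, cholesterol, horizon,
      paste(sort(unique(valid$level)), collapse = ", ")
    ), class = "ocm_error_lookup")
  }
  hit
}
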
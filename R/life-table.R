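#' Life tables: age-specific baseline risk of other-cause death
#'
#' A life table here is a tibble with columns `age` (integer, contiguous) and
#' `risk` (probability of death by the table's horizon), carrying attributes
#' `horizon` (10 or 15 years) and `source_label`. The packaged table holds
#' Social Security Administration (SSA) risks for ages 50-75 together with the
#' model's adjusted risks, which shift the SSA risks down by 3 years of age
#' because men presenting with localized prostate cancer are, on average,
#' healthier than the general male population of the same age.
#'
#' @name life_tables
NULL

new_life_table <- function(age, risk, horizon, source_label) {
  out <- tibble(age = as.integer(age), risk = as.numeric(risk))
  attr(out, "horizon") <- horizon
  attr(out, "source_label") <- source_label
  class(out) <- c("ocm_life_table", class(out))
  validate_life_table(out)
}

validate_life_table <- function(table) {
  age <- table$age
  risk <- table$risk
  if (any(is.na(age)) || any(is.na(risk))) {
    stop_input("life table contains missing ages or risks")
  }
  full <- seq(min(age), max(age))
  missing_ages <- setdiff(full, age)
  if (length(missing_ages) > 0) {
    stop_input(sprintf(
      "life table ages are not contiguous: missing age(s) %s",
      paste(missing_ages, collapse = ", ")
    ), class = "ocm_error_life_table")
  }
  if (anyDuplicated(age)) {
    stop_input("life table contains duplicated ages", class = "ocm_error_life_table")
  }
  if (any(risk < 0 | risk > 1)) {
    stop_input("life table risks must lie in [0, 1]", class = "ocm_error_life_table")
  }
  ord <- order(age)
  if (is.unsorted(risk[ord])) {
    bad <- age[ord][which(diff(risk[ord]) < 0)]
    stop_input(sprintf(
      "life table risk decreases with age after age(s) %s; refusing to load (data-entry guard)",
      paste(bad, collapse = ", ")
    ), class = "ocm_error_life_table")
  }
  table[ord, ]
}

#' Load a life table from a delimited text file
#'
#' The file must have one row per integer age with percent risks at both
#' horizons in both the raw (SSA) and adjusted columns: `age`, `ssa_10y`,
#' `adj_10y`, `ssa_15y`, `adj_15y`. Percents are converted to probabilities on
#' load, ages must be contiguous, and risk must be non-decreasing in age.
#'
#' @param path Path to the CSV file. Defaults to the packaged table.
#' @param horizon Prediction horizon in years, 10 or 15.
#' @param column `"adjusted"` for the model's (age-shifted) baseline,
#'   `"raw"` for the unshifted SSA column.
#' @return A life table (tibble with columns `age`, `risk`; attributes
#'   `horizon`, `source_label`).
#' @examples
#' lt <- load_life_table(horizon = 10, column = "adjusted")
#' baseline_risk(lt, 65) # 0.18
#' @export
load_life_table <- function(path = NULL, horizon = c(10, 15),
                            column = c("adjusted", "raw")) {
  horizon <- as.numeric(match.arg(as.character(horizon[1]), c("10", "15")))
  column <- match.arg(column)
  path <- path %||% ocm_extdata("ssa_life_table.csv")
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()))
  col <- sprintf("%s_%dy", if (column == "adjusted") "adj" else "ssa", horizon)
  needed <- c("age", col)
  if (!all(needed %in% names(raw))) {
    stop_input(sprintf("life table file lacks column(s): %s",
                       paste(setdiff(needed, names(raw)), collapse = ", ")))
  }
  new_life_table(
    age = raw$age,
    risk = raw[[col]] / 100,
    horizon = horizon,
    source_label = sprintf("%s (%s, %d-year)", basename(path), column, horizon)
  )
}

#' Shift a life table down in age
#'
#' Produces the "healthier-than-average" adjustment: the shifted table assigns
#' to age `a` the raw table's risk at age `a - shift`. Ages whose source would
#' fall below the raw table's range are dropped, so the output starts at
#' `age_min + shift`.
#'
#' @param table A life table, normally loaded with `column = "raw"`.
#' @param shift Non-negative integer number of years (default 3).
#' @return A life table covering ages `age_min + shift` to `age_max`.
#' @examples
#' raw10 <- load_life_table(horizon = 10, column = "raw")
#' shifted <- shift_life_table(raw10, 3)
#' baseline_risk(shifted, 53) # equals baseline_risk(raw10, 50)
#' @export
shift_life_table <- function(table, shift = 3) {
  stopifnot(inherits(table, "ocm_life_table"))
  if (length(shift) != 1 || is.na(shift) || shift < 0 || shift != floor(shift)) {
    stop_input("shift must be a single non-negative integer")
  }
  shift <- as.integer(shift)
  if (shift == 0) return(table)
  span <- max(table$age) - min(table$age)
  if (shift > span) {
    stop_input(sprintf("shift of %d years exceeds the table's %d-year age span", shift, span))
  }
  new_life_table(
    age = table$age[seq_len(nrow(table) - shift)] + shift,
    risk = table$risk[seq_len(nrow(table) - shift)],
    horizon = attr(table, "horizon"),
    source_label = sprintf("%s shifted -%dy", attr(table, "source_label"), shift)
  )
}

#' Baseline risk of other-cause death for a given age
#'
#' Exact lookup in a life table. Non-integer ages are floored to completed
#' years (life tables are defined on completed age). Ages above the table
#' maximum clamp to the oldest available row with a warning; ages below the
#' minimum are an error, never a silent extrapolation.
#'
#' @param table A life table.
#' @param age Age(s) in years.
#' @param horizon Optional; if supplied, must match the table's horizon
#'   (guards against pairing a 10-year table with a 15-year question).
#' @return Numeric vector of probabilities.
#' @export
baseline_risk <- function(table, age, horizon = NULL) {
  stopifnot(inherits(table, "ocm_life_table"))
  if (!is.null(horizon) && !identical(as.numeric(horizon), as.numeric(attr(table, "horizon")))) {
    stop_input(sprintf("requested horizon %s does not match the table's %s-year horizon",
                       horizon, attr(table, "horizon")))
  }
  if (any(is.na(age))) stop_input("age contains missing values")
  age <- floor(age)
  amin <- min(table$age)
  amax <- max(table$age)
  if (any(age < amin)) {
    stop_input(sprintf(
      "age(s) %s below the life table's supported minimum of %d",
      paste(unique(age[age < amin]), collapse = ", "), amin
    ), class = "ocm_error_age_range")
  }
  if (any(age > amax)) {
    warn(sprintf(
      "age(s) above %d clamped to %d (risk is likely underestimated for the oldest patients)",
      amax, amax
    ), class = "ocm_warning_age_clamp")
    age <- pmin(age, amax)
  }
  table$risk[match(age, table$age)]
}

#' @export
print.ocm_life_table <- function(x, ...) {
  cat(sprintf("<life table: %s, ages %d-%d>\n",
              attr(x, "source_label"), min(x$age), max(x$age)))
  NextMethod()
}
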
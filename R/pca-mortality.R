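#' Untreated prostate-cancer mortality and competing-risk adjustment
#'
#' Tables of prostate-cancer death probability under conservative management
#' (no curative treatment) are indexed by risk group (low / intermediate /
#' high, assigned from clinical stage and Gleason grade only — PSA is
#' deliberately excluded) and age band. Because such tables were typically
#' built on cohorts graded before the Gleason grading shift of the early
#' 2000s, [regrade_adjust()] deconvolves the historical low-risk group into a
#' contemporary one. [conditional_pc_mortality()] then discounts the
#' untreated prostate-cancer risk by the probability of first dying of
#' another cause.
#'
#' The packaged file `untreated_pc_mortality_synthetic.csv` is a synthetic
#' example table with plausible magnitudes; it is a stand-in for published
#' conservative-management estimates, which users should supply themselves.
#'
#' @name pca_mortality
NULL

#' Load an untreated prostate-cancer mortality table
#'
#' @param path CSV with columns `risk_group` (low/intermediate/high),
#'   `age_band` (labels like `"<65"`, `"65-74"`, `"75+"`), `horizon`, `risk`.
#'   Default: the packaged synthetic example table.
#' @return Tibble of class `ocm_untreated_table`. On load it is checked that
#'   probabilities lie in \[0, 1\] and that within each (age band, horizon)
#'   low <= intermediate <= high.
#' @export
load_untreated_table <- function(path = NULL) {
  path <- path %||% ocm_extdata("untreated_pc_mortality_synthetic.csv")
  tab <- readr::read_csv(path, col_types = readr::cols(
    risk_group = readr::col_character(),
    age_band = readr::col_character(),
    horizon = readr::col_double(),
    risk = readr::col_double()
  ))
  validate_untreated_table(tab)
}

validate_untreated_table <- function(tab) {
  groups <- c("low", "intermediate", "high")
  if (!all(tab$risk_group %in% groups)) {
    stop_input(sprintf("risk_group must be one of: %s", paste(groups, collapse = ", ")))
  }
  if (any(is.na(tab$risk)) || any(tab$risk < 0 | tab$risk > 1)) {
    stop_input("untreated risks must lie in [0, 1]")
  }
  wide <- tidyr::pivot_wider(tab, names_from = "risk_group", values_from = "risk")
  if (!all(c("low", "intermediate", "high") %in% names(wide)) ||
      any(is.na(wide$low)) || any(is.na(wide$intermediate)) || any(is.na(wide$high))) {
    stop_input("each (age_band, horizon) needs all three risk groups")
  }
  if (any(wide$low > wide$intermediate | wide$intermediate > wide$high)) {
    stop_input("untreated risks must satisfy low <= intermediate <= high within each age band")
  }
  if (!inherits(tab, "ocm_untreated_table")) {
    class(tab) <- c("ocm_untreated_table", class(tab))
  }
  tab
}

#' Assign a risk group from stage and grade
#'
#' Deterministic mapping from clinical stage and (collapsed) Gleason grade to
#' low / intermediate / high risk. PSA is never consulted: once stage and
#' grade are known, PSA adds little prognostic information in diagnosed
#' localized disease. The default rule: Gleason >= 8 or stage T3/T4 is high;
#' Gleason <= 6 with organ-confined stage (T1/T2) is low; everything else
#' (Gleason 7, organ-confined) is intermediate. The boundaries are
#' configuration-driven via `high_stages` / `low_stages` so users can match
#' the grouping of whichever untreated-mortality table they supply.
#'
#' @param tumors Data frame with columns `clinical_stage` and `gleason`
#'   (levels `"<=6"`, `"7"`, `">=8"`; 3+4 and 4+3 are collapsed to 7).
#' @param low_stages,high_stages Character vectors of stage labels counted as
#'   organ-confined and locally advanced respectively.
#' @return Character vector in `c("low", "intermediate", "high")`.
#' @examples
#' assign_risk_group(data.frame(clinical_stage = "T1", gleason = "<=6")) # low
#' @export
assign_risk_group <- function(tumors,
                              low_stages = c("T1", "T2", "T2a", "T2b", "T2c"),
                              high_stages = c("T3", "T3a", "T3b", "T4")) {
  if (!is.data.frame(tumors) || !all(c("clinical_stage", "gleason") %in% names(tumors))) {
    stop_input("tumors must be a data frame with columns clinical_stage and gleason")
  }
  gl <- as.character(tumors$gleason)
  st <- as.character(tumors$clinical_stage)
  bad_gl <- setdiff(unique(gl), c("<=6", "7", ">=8"))
  if (length(bad_gl) > 0) {
    stop_input(sprintf("unknown gleason level(s) %s; valid: <=6, 7, >=8",
                       paste(bad_gl, collapse = ", ")))
  }
  bad_st <- setdiff(unique(st), c(low_stages, high_stages))
  if (length(bad_st) > 0) {
    stop_input(sprintf("unknown clinical_stage level(s) %s; valid: %s",
                       paste(bad_st, collapse = ", "),
                       paste(c(low_stages, high_stages), collapse = ", ")))
  }
  dplyr::case_when(
    gl == ">=8" ~ "high",
    st %in% high_stages ~ "high",
    gl == "7" ~ "intermediate",
    TRUE ~ "low"
  )
}

#' Adjust an untreated-mortality table for contemporary Gleason grading
#'
#' Historical cohorts graded before the early-2000s grading shift scored many
#' tumors Gleason 6 that would be Gleason 7 today. Assuming a fraction `f`
#' (default 0.25) of the historical low-risk group would be upgraded, and
#' that upgraded patients carry a risk equal to the average of the historical
#' low and intermediate groups, the historical low-group risk is the mixture
#'
#'   r_low_old = (1 - f) * r_low_new + f * (r_low_old + r_int_old) / 2
#'
#' which is solved for the contemporary low-group risk `r_low_new`.
#' Intermediate and high groups pass through unchanged.
#'
#' @param table An `ocm_untreated_table`.
#' @param upgrade_fraction Fraction of the historical low group upgraded,
#'   in \[0, 1).
#' @return The adjusted table, with an attribute `upgraded` holding a tibble
#'   of the upgraded subgroup's risks per (age band, horizon).
#' @examples
#' tab <- load_untreated_table()
#' regrade_adjust(tab, 0.25)
#' @export
regrade_adjust <- function(table, upgrade_fraction = 0.25) {
  table <- validate_untreated_table(table)
  f <- upgrade_fraction
  if (length(f) != 1 || is.na(f) || f < 0 || f >= 1) {
    stop_input("upgrade_fraction must lie in [0, 1)")
  }
  wide <- tidyr::pivot_wider(table, names_from = "risk_group", values_from = "risk")
  upgraded <- (wide$low + wide$intermediate) / 2
  low_new <- (wide$low - f * upgraded) / (1 - f)
  if (any(low_new < 0)) {
    stop_input("deconvolved contemporary low-group risk is negative; the input table is inconsistent with the assumed upgrade fraction")
  }
  out <- table
  is_low <- out$risk_group == "low"
  key_in <- paste(out$age_band, out$horizon)
  key_wide <- paste(wide$age_band, wide$horizon)
  out$risk[is_low] <- low_new[match(key_in[is_low], key_wide)]
  out <- validate_untreated_table(out)
  attr(out, "upgraded") <- tibble(age_band = wide$age_band, horizon = wide$horizon,
                                  risk = upgraded)
  attr(out, "upgrade_fraction") <- f
  out
}

#' Look up untreated risk for a patient
#'
#' Maps an age to the table's age band (labels `"<hi"`, `"lo-hi"`, `"lo+"`)
#' and returns the risk for the given group and horizon.
#'
#' @param table An `ocm_untreated_table`.
#' @param risk_group,age,horizon Vectors (recycled to a common length).
#' @return Numeric vector of probabilities.
#' @export
lookup_untreated_risk <- function(table, risk_group, age, horizon = 15) {
  table <- validate_untreated_table(table)
  bands <- unique(table$age_band)
  band_of <- function(a) {
    for (b in bands) {
      if (grepl("^<", b)) {
        if (a < as.numeric(sub("^<", "", b))) return(b)
      } else if (grepl("\\+$", b)) {
        if (a >= as.numeric(sub("\\+$", "", b))) return(b)
      } else if (grepl("-", b)) {
        lim <- as.numeric(strsplit(b, "-")[[1]])
        if (a >= lim[1] && a <= lim[2]) return(b)
      }
    }
    stop_input(sprintf("no age band covers age %s (bands: %s)", a,
                       paste(bands, collapse = ", ")))
  }
  args <- vctrs_recycle(risk_group, age, horizon)
  purrr::pmap_dbl(args, function(g, a, h) {
    hit <- table$risk[table$risk_group == g & table$age_band == band_of(a) &
                        table$horizon == h]
    if (length(hit) != 1) {
      stop_input(sprintf("no untreated risk for group '%s', age %s, horizon %s", g, a, h))
    }
    hit
  })
}

vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, rep_len, length.out = n)
}

#' Prostate-cancer mortality conditional on surviving other causes
#'
#' The probability of dying of prostate cancer under conservative management,
#' taking into account the competing probability of first dying of another
#' cause: `(1 - ocm_risk) * untreated_pc_risk`. The result never exceeds the
#' untreated risk and the sum with the other-cause risk never exceeds 1.
#'
#' @param ocm_risk Comorbidity-adjusted other-cause mortality probability.
#' @param untreated_pc_risk Untreated prostate-cancer mortality probability.
#' @return Numeric vector of probabilities.
#' @examples
#' conditional_pc_mortality(0.40, 0.20) # 0.12
#' @export
conditional_pc_mortality <- function(ocm_risk, untreated_pc_risk) {
  if (any(is.na(ocm_risk)) || any(ocm_risk < 0 | ocm_risk > 1)) {
    stop_input("ocm_risk must lie in [0, 1]")
  }
  if (any(is.na(untreated_pc_risk)) || any(untreated_pc_risk < 0 | untreated_pc_risk > 1)) {
    stop_input("untreated_pc_risk must lie in [0, 1]")
  }
  (1 - ocm_risk) * untreated_pc_risk
}
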
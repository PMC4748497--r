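#' Cohort pipeline: predict, validate, simulate, report
#'
#' File-in, file-out driver behind the command-line tool. All tabular I/O is
#' delimited text (comma by default, tab selectable via `config$delim`).
#'
#' Commands:
#' * `predict`: read patient records, append baseline risk, combined odds
#'   ratio and adjusted risk at both horizons, write `predictions.csv`.
#' * `validate`: read a cohort with predictions, follow-up and an event code
#'   (0 censored / 1 other-cause death / 2 prostate-cancer death, the latter
#'   censored by default; set `config$pc_deaths = "event"` for all-cause),
#'   write `validation_summary.csv` (c-index per horizon) and
#'   `calibration.csv` (bins).
#' * `simulate`: generate a synthetic cohort with simulated outcomes
#'   (`config$n`, `config$seed`, `config$censor_horizon`), write
#'   `simulated_cohort.csv`. `input` is ignored.
#' * `report`: per-patient narrative reports for every row of the input,
#'   written to `reports.txt`.
#'
#' The `predict` output re-reads as `validate` input without transformation
#' (validate falls back to the `adjusted_risk_<h>y` columns when no
#' `predicted_risk_<h>y` columns are present).
#'
#' @param input Path to the input file (ignored for `simulate`).
#' @param command One of `"predict"`, `"validate"`, `"simulate"`, `"report"`.
#' @param config Named list: `delim`, `horizons`, `n_bins`, `pc_deaths`,
#'   `n`, `seed`, `censor_horizon`, `shift_years`, `life_table_path`,
#'   `or_path`.
#' @param output_dir Directory for output files (created if needed).
#' @return Invisibly, a list with `status` (0 on success), `outputs` (paths
#'   written) and command-specific results; errors raise conditions carrying
#'   class `ocm_error_input` (bad data, exit 1) or `ocm_error_config`
#'   (bad invocation, exit 2).
#' @export
run_cohort_pipeline <- function(input, command = c("predict", "validate", "simulate", "report"),
                                config = list(), output_dir = ".") {
  command <- tryCatch(match.arg(command),
                      error = function(e) abort(sprintf("unknown command '%s'", command[1]),
                                                class = "ocm_error_config"))
  delim <- config$delim %||% ","
  horizons <- config$horizons %||% c(10, 15)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  model <- ocm_model(life_table_path = config$life_table_path,
                     or_path = config$or_path,
                     shift_years = config$shift_years %||% 3)
  outputs <- character(0)
  result <- list()

  if (command %in% c("predict", "validate", "report")) {
    if (is.null(input) || !file.exists(input)) {
      abort(sprintf("input file not found: %s", input %||% "<missing>"),
            class = "ocm_error_config")
    }
  }

  if (command == "predict") {
    patients <- read_patients(input, delim = delim)
    pred <- predict_ocm(patients, model = model, horizons = horizons)
    path <- file.path(output_dir, "predictions.csv")
    readr::write_delim(pred, path, delim = delim)
    outputs <- path
    result$predictions <- pred
    message(sprintf("predict: %d patients -> %s", nrow(pred), path))
  } else if (command == "validate") {
    cohort <- readr::read_delim(input, delim = delim, col_types = readr::cols(),
                                show_col_types = FALSE)
    if (!"followup_years" %in% names(cohort)) {
      abort("validate input needs a followup_years column", class = "ocm_error_input")
    }
    if ("event_code" %in% names(cohort)) {
      cohort$event <- recode_events(cohort$event_code,
                                    pc_deaths = config$pc_deaths %||% "censor")
    }
    if (!"event" %in% names(cohort)) {
      abort("validate input needs an event or event_code column", class = "ocm_error_input")
    }
    for (h in horizons) {
      pcol <- sprintf("predicted_risk_%dy", h)
      acol <- sprintf("adjusted_risk_%dy", h)
      if (!pcol %in% names(cohort) && acol %in% names(cohort)) cohort[[pcol]] <- cohort[[acol]]
    }
    val <- validate_cohort(cohort, horizons = horizons,
                           n_bins = config$n_bins %||% 10)
    sum_path <- file.path(output_dir, "validation_summary.csv")
    cal_path <- file.path(output_dir, "calibration.csv")
    readr::write_delim(glance(val), sum_path, delim = delim)
    readr::write_delim(tidy(val), cal_path, delim = delim)
    outputs <- c(sum_path, cal_path)
    result$validation <- val
    message(paste(utils::capture.output(print(val$summary)), collapse = "\n"))
  } else if (command == "simulate") {
    spec <- cohort_spec(n = config$n %||% 1000, seed = config$seed %||% 1L,
                        censor_horizon = config$censor_horizon %||% 18)
    cohort <- simulate_outcomes(generate_cohort(spec), model = model,
                                seed = spec$seed + 1L,
                                censor_horizon = spec$censor_horizon)
    path <- file.path(output_dir, "simulated_cohort.csv")
    readr::write_delim(cohort, path, delim = delim)
    outputs <- path
    result$cohort <- cohort
    message(sprintf("simulate: %d patients -> %s", nrow(cohort), path))
  } else if (command == "report") {
    patients <- read_patients(input, delim = delim)
    path <- file.path(output_dir, "reports.txt")
    txt <- vapply(seq_len(nrow(patients)), function(i) {
      rep_i <- compute_patient_report(patients[i, ], model = model)
      paste(utils::capture.output(print(rep_i)), collapse = "\n")
    }, character(1))
    writeLines(paste(txt, collapse = "\n\n"), path)
    outputs <- path
    message(sprintf("report: %d patients -> %s", nrow(patients), path))
  }

  invisible(list(status = 0L, command = command, outputs = outputs, result = result))
}
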
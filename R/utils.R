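#' Round to whole percent, half away from zero
#'
#' Converts a probability to a whole-number percentage using round-half-up,
#' the convention used for display throughout the package (so 0.305 prints
#' as 31, not 30). Internal arithmetic is never rounded.
#'
#' @param p Numeric vector of probabilities in \[0, 1\].
#' @return Integer vector of percentages.
#' @examples
#' percent_round(c(0.305, 0.2539, 0.4049))
#' @export
percent_round <- function(p) {
  stopifnot(is.numeric(p))
  as.integer(floor(p * 100 + 0.5))
}

# path to a packaged data file, erroring with a clear message if absent
ocm_extdata <- function(file) {
  path <- system.file("extdata", file, package = "ocmrisk")
  if (!nzchar(path)) {
    abort(sprintf("packaged data file '%s' not found; is ocmrisk installed correctly?", file),
          class = "ocm_error_config")
  }
  path
}

stop_input <- function(msg, class = "ocm_error_input") abort(msg, class = class)
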
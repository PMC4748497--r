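#' Patient comorbidity profiles
#'
#' A patient record is one row of a data frame with an `age` column plus the
#' comorbidity fields below. Flags are logical (or 0/1); categorical fields
#' take exactly one of the listed levels. Cholesterol flags are modifiers
#' only: they scale the odds ratio of cholesterol-sensitive comorbidities and
#' carry no standalone risk.
#'
#' * flags: `hypertension` (systolic >= 160 and diastolic >= 90), `angina`,
#'   `congestive_heart_failure`, `heart_attack`, `aortic_stenosis`,
#'   `atrial_fibrillation`, `abdominal_aortic_aneurysm`,
#'   `peripheral_vascular_disease`, `deep_venous_thrombosis`,
#'   `pulmonary_embolus`, `high_total_cholesterol` (> 270 mg/dL),
#'   `low_hdl` (< 20 mg/dL)
#' * `asthma`: none, mild, moderate, severe
#' * `stroke`: none, hemorrhage, infarction
#' * `smoking`: never, former, current
#' * `diabetes`: none, 0-5, 6-10, 11-20, >20 (years since diagnosis)
#'
#' @name comorbidity_profiles
NULL

profile_flag_fields <- c(
  "hypertension", "angina", "congestive_heart_failure", "heart_attack",
  "aortic_stenosis", "atrial_fibrillation", "abdominal_aortic_aneurysm",
  "peripheral_vascular_disease", "deep_venous_thrombosis", "pulmonary_embolus",
  "high_total_cholesterol", "low_hdl"
)

profile_categorical_levels <- list(
  asthma = c("none", "mild", "moderate", "severe"),
  stroke = c("none", "hemorrhage", "infarction"),
  smoking = c("never", "former", "current"),
  diabetes = c("none", "0-5", "6-10", "11-20", ">20")
)

profile_fields <- function() c(profile_flag_fields, names(profile_categorical_levels))

#' Build a one-row patient profile
#'
#' Convenience constructor with every comorbidity defaulting to absent.
#'
#' @param age Age in years.
#' @param ... Profile fields to override, e.g. `smoking = "current"`,
#'   `angina = TRUE`.
#' @return A one-row tibble passing [validate_patients()].
#' @examples
#' ocm_profile(65, smoking = "current", angina = TRUE)
#' @export
ocm_profile <- function(age, ...) {
  defaults <- c(
    setNames(as.list(rep(FALSE, length(profile_flag_fields))), profile_flag_fields),
    lapply(profile_categorical_levels, function(lv) lv[1])
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    stop_input(sprintf("unknown profile field(s): %s", paste(unknown, collapse = ", ")))
  }
  defaults[names(over)] <- over
  validate_patients(as_tibble(c(list(age = age), defaults)))
}

#' Validate a patient data frame
#'
#' Checks the schema of per-patient records: `age` present and numeric, flag
#' columns coercible to logical, categorical columns restricted to their
#' enumerations. Columns that are absent are filled with "absent" defaults
#' (FALSE / none / never), mirroring cohorts that record only a subset of the
#' model's comorbidities. Violations are reported together, each naming the
#' field and the offending row numbers.
#'
#' @param patients A data frame of patient records.
#' @return The validated tibble with all profile columns present and typed.
#' @export
validate_patients <- function(patients) {
  if (!is.data.frame(patients)) stop_input("patients must be a data frame")
  patients <- as_tibble(patients)
  problems <- character(0)
  if (!"age" %in% names(patients)) {
    problems <- c(problems, "missing required column 'age'")
  } else if (!is.numeric(patients$age) || any(is.na(patients$age))) {
    problems <- c(problems, "'age' must be numeric with no missing values")
  }
  for (f in profile_flag_fields) {
    if (!f %in% names(patients)) {
      patients[[f]] <- FALSE
      next
    }
    v <- patients[[f]]
    if (is.numeric(v) && all(v %in% c(0, 1))) v <- v == 1
    if (!is.logical(v) || any(is.na(v))) {
      problems <- c(problems, sprintf("'%s' must be logical (or 0/1) with no missing values", f))
    } else {
      patients[[f]] <- v
    }
  }
  for (f in names(profile_categorical_levels)) {
    levels <- profile_categorical_levels[[f]]
    if (!f %in% names(patients)) {
      patients[[f]] <- levels[1]
      next
    }
    v <- as.character(patients[[f]])
    bad <- which(is.na(v) | !v %in% levels)
    if (length(bad) > 0) {
      problems <- c(problems, sprintf(
        "'%s' has invalid level(s) %s at row(s) %s; valid levels: %s",
        f, paste(unique(v[bad]), collapse = ", "),
        paste(head(bad, 5), collapse = ", "), paste(levels, collapse = ", ")
      ))
    } else {
      patients[[f]] <- v
    }
  }
  if (length(problems) > 0) {
    abort(c("invalid patient records:", setNames(problems, rep("x", length(problems)))),
          class = "ocm_error_schema")
  }
  patients
}

#' Read patient records from delimited text
#'
#' @param path Path to a delimited file with one row per patient.
#' @param delim Field delimiter (`","` default, `"\t"` selectable).
#' @return A validated patient tibble.
#' @export
read_patients <- function(path, delim = ",") {
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           show_col_types = FALSE)
  validate_patients(raw)
}

# cholesterol modifier state per patient row
cholesterol_state <- function(patients) {
  dplyr::case_when(
    patients$high_total_cholesterol & patients$low_hdl ~ "both",
    patients$high_total_cholesterol ~ "high_total",
    patients$low_hdl ~ "low_hdl",
    TRUE ~ "none"
  )
}

# long table of active comorbidity factors: one row per (patient, comorbidity)
active_factors <- function(patients) {
  idx <- seq_len(nrow(patients))
  parts <- list()
  for (f in setdiff(profile_flag_fields, c("high_total_cholesterol", "low_hdl"))) {
    on <- which(patients[[f]])
    if (length(on) > 0) {
      parts[[f]] <- tibble(patient = on, comorbidity = f, level = "present")
    }
  }
  for (f in names(profile_categorical_levels)) {
    base <- profile_categorical_levels[[f]][1] # none / never
    on <- which(patients[[f]] != base)
    if (length(on) > 0) {
      parts[[f]] <- tibble(patient = on, comorbidity = f, level = patients[[f]][on])
    }
  }
  if (length(parts) == 0) {
    return(tibble(patient = integer(0), comorbidity = character(0), level = character(0)))
  }
  bind_rows(parts)
}
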
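#' Per-patient clinical report
#'
#' Computes everything the counseling report needs for one patient: baseline
#' and comorbidity-adjusted other-cause mortality at 10 and 15 years with the
#' combined odds ratios and the per-comorbidity audit trail, and — when a
#' tumor classification and an untreated-mortality table are supplied — the
#' risk group, untreated prostate-cancer mortality, and the
#' conditional prostate-cancer mortality discounted for competing other-cause
#' death. Patients whose 10-year other-cause risk exceeds 50% are processed
#' like any other: a short life expectancy is exactly when the estimate
#' matters for choosing conservative management.
#'
#' @param patient A one-row patient data frame (see [ocm_profile()]).
#' @param model An [ocm_model()]; defaults when `NULL`.
#' @param tumor Optional one-row data frame with `clinical_stage` and
#'   `gleason` (see [assign_risk_group()]).
#' @param untreated_table Optional `ocm_untreated_table`; required for the
#'   prostate-cancer block. Apply [regrade_adjust()] beforehand if the table
#'   predates contemporary Gleason grading.
#' @param pc_horizon Horizon (years) of the untreated table (default 15).
#' @return An object of class `ocm_report`; `print()` renders the narrative,
#'   `tidy()` the structured numbers. Every number in the narrative equals
#'   the corresponding structured field after whole-percent rounding.
#' @examples
#' compute_patient_report(ocm_profile(65, smoking = "current"))
#' @export
compute_patient_report <- function(patient, model = NULL, tumor = NULL,
                                   untreated_table = NULL, pc_horizon = 15) {
  patient <- validate_patients(patient)
  if (nrow(patient) != 1) stop_input("compute_patient_report() takes a single patient")
  model <- model %||% ocm_model()
  estimates <- lapply(c(`10` = 10, `15` = 15), function(h) {
    base <- baseline_risk(model$life_tables[[as.character(h)]], patient$age)
    adjusted_risk(base, patient, model$or_table, horizon = h)
  })
  pc <- NULL
  if (!is.null(tumor)) {
    if (is.null(untreated_table)) {
      stop_input("a tumor classification was given without an untreated-mortality table")
    }
    group <- assign_risk_group(tumor)
    untreated <- lookup_untreated_risk(untreated_table, group, patient$age, pc_horizon)
    ocm_at_h <- estimates[[as.character(pc_horizon)]]$adjusted_risk
    pc <- list(
      risk_group = group,
      horizon = pc_horizon,
      untreated_pc_risk = untreated,
      ocm_risk = ocm_at_h,
      conditional_pc_risk = conditional_pc_mortality(ocm_at_h, untreated)
    )
  }
  structure(list(patient = patient, tumor = tumor, estimates = estimates,
                 prostate_cancer = pc),
            class = "ocm_report")
}

report_comorbidity_phrases <- function(patient) {
  phr <- character(0)
  labels <- c(
    hypertension = "hypertension", angina = "angina",
    congestive_heart_failure = "congestive heart failure",
    heart_attack = "prior heart attack", aortic_stenosis = "aortic stenosis",
    atrial_fibrillation = "atrial fibrillation",
    abdominal_aortic_aneurysm = "abdominal aortic aneurysm",
    peripheral_vascular_disease = "peripheral vascular disease",
    deep_venous_thrombosis = "deep venous thrombosis",
    pulmonary_embolus = "pulmonary embolus",
    high_total_cholesterol = "high total cholesterol",
    low_hdl = "low HDL cholesterol"
  )
  for (f in names(labels)) if (isTRUE(patient[[f]])) phr <- c(phr, labels[[f]])
  if (patient$asthma != "none") phr <- c(phr, sprintf("%s asthma", patient$asthma))
  if (patient$stroke != "none") phr <- c(phr, sprintf("stroke (%s)", patient$stroke))
  if (patient$smoking != "never") phr <- c(phr, sprintf("%s smoker", patient$smoking))
  if (patient$diabetes != "none") phr <- c(phr, sprintf("diabetes (%s years)", patient$diabetes))
  phr
}

#' @export
print.ocm_report <- function(x, ...) {
  p <- x$patient
  phr <- report_comorbidity_phrases(p)
  cat(sprintf("Patient: %d-year-old man; %s.\n", as.integer(p$age),
              if (length(phr)) paste(phr, collapse = ", ") else "no recorded comorbidities"))
  for (h in c("10", "15")) {
    est <- x$estimates[[h]]
    cat(sprintf(
      "%s-year other-cause mortality: baseline %d%%, adjusted %d%% (combined odds ratio %.2f).\n",
      h, percent_round(est$baseline_risk), percent_round(est$adjusted_risk),
      est$combined_odds_ratio
    ))
  }
  if (!is.null(x$prostate_cancer)) {
    pc <- x$prostate_cancer
    cat(sprintf(
      "Tumor: stage %s, Gleason %s -> %s risk.\n",
      x$tumor$clinical_stage, x$tumor$gleason, pc$risk_group
    ))
    cat(sprintf(
      "%d-year prostate-cancer mortality if managed conservatively: %d%% untreated; %d%% after accounting for the %d%% risk of death from other causes.\n",
      pc$horizon, percent_round(pc$untreated_pc_risk),
      percent_round(pc$conditional_pc_risk), percent_round(pc$ocm_risk)
    ))
  }
  invisible(x)
}
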
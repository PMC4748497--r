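test_that("the patient report reproduces the worked counseling numbers", {
  rep1 <- compute_patient_report(ocm_profile(65, smoking = "current"))
  expect_equal(percent_round(rep1$estimates[["10"]]$adjusted_risk), 31)
  txt <- paste(capture.output(print(rep1)), collapse = "\n")
  expect_match(txt, "baseline 18%, adjusted 31%")
  expect_match(txt, "current smoker")

  rep0 <- compute_patient_report(ocm_profile(65))
  expect_identical(rep0$estimates[["10"]]$adjusted_risk,
                   rep0$estimates[["10"]]$baseline_risk)
  expect_match(paste(capture.output(print(rep0)), collapse = "\n"),
               "baseline 18%, adjusted 18%")
})

test_that("narrative numbers equal structured fields after display rounding", {
  rep <- compute_patient_report(
    ocm_profile(71, congestive_heart_failure = TRUE, smoking = "former"),
    tumor = data.frame(clinical_stage = "T2", gleason = "7"),
    untreated_table = load_untreated_table()
  )
  txt <- paste(capture.output(print(rep)), collapse = "\n")
  td <- tidy(rep)
  for (h in c(10, 15)) {
    est <- rep$estimates[[as.character(h)]]
    expect_match(txt, sprintf("baseline %d%%, adjusted %d%%",
                              percent_round(est$baseline_risk),
                              percent_round(est$adjusted_risk)))
  }
  pc <- rep$prostate_cancer
  expect_equal(pc$conditional_pc_risk,
               conditional_pc_mortality(pc$ocm_risk, pc$untreated_pc_risk))
  expect_match(txt, sprintf("%d%% untreated; %d%% after",
                            percent_round(pc$untreated_pc_risk),
                            percent_round(pc$conditional_pc_risk)))
  expect_identical(td$risk_group[1], "intermediate")
})

test_that("high-risk patients are fully processed, not refused", {
  sick <- ocm_profile(75, congestive_heart_failure = TRUE, stroke = "infarction",
                      smoking = "current")
  rep <- compute_patient_report(sick)
  expect_gt(rep$estimates[["10"]]$adjusted_risk, 0.5)
  expect_error(compute_patient_report(ocm_profile(65, smoking = "sometimes")),
               class = "ocm_error_schema")
})

test_that("predict writes one row per patient with the four risk columns", {
  out_dir <- withr::local_tempdir()
  fixture <- system.file("extdata", "example_patients.csv", package = "ocmrisk")
  res <- suppressMessages(run_cohort_pipeline(fixture, "predict", output_dir = out_dir))
  expect_identical(res$status, 0L)
  pred <- readr::read_csv(res$outputs, show_col_types = FALSE)
  expect_equal(nrow(pred), 3)
  expect_true(all(c("baseline_risk_10y", "adjusted_risk_10y",
                    "baseline_risk_15y", "adjusted_risk_15y") %in% names(pred)))
  expect_equal(percent_round(pred$adjusted_risk_10y[1]), 31) # 65-year-old smoker
})

test_that("simulate is reproducible and its output validates round-trip", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- list(n = 600, seed = 5, censor_horizon = 18)
  suppressMessages(run_cohort_pipeline(NULL, "simulate", cfg, output_dir = d1))
  suppressMessages(run_cohort_pipeline(NULL, "simulate", cfg, output_dir = d2))
  expect_identical(readLines(file.path(d1, "simulated_cohort.csv")),
                   readLines(file.path(d2, "simulated_cohort.csv")))
  res <- suppressMessages(run_cohort_pipeline(file.path(d1, "simulated_cohort.csv"),
                                              "validate", output_dir = d1))
  expect_true(all(file.exists(res$outputs)))
  summ <- readr::read_csv(file.path(d1, "validation_summary.csv"),
                          show_col_types = FALSE)
  expect_true(all(summ$c_index > 0.5)) # true signal in model-generated data
  cal <- readr::read_csv(file.path(d1, "calibration.csv"), show_col_types = FALSE)
  expect_equal(sort(unique(cal$horizon)), c(10, 15))
})

test_that("pipeline errors distinguish bad input from bad invocation", {
  out_dir <- withr::local_tempdir()
  bad <- file.path(out_dir, "bad.csv")
  writeLines(c("age,smoking", "65,maybe"), bad)
  expect_error(suppressMessages(run_cohort_pipeline(bad, "predict", output_dir = out_dir)),
               class = "ocm_error_schema")
  expect_error(run_cohort_pipeline(bad, "frobnicate", output_dir = out_dir),
               class = "ocm_error_config")
  expect_error(run_cohort_pipeline(file.path(out_dir, "absent.csv"), "predict",
                                   output_dir = out_dir),
               class = "ocm_error_config")
})
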
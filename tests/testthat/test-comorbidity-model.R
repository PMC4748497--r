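ors <- load_odds_ratio_table()

test_that("risk-odds conversion matches the 18:82 worked arithmetic and inverts exactly", {
  expect_equal(risk_to_odds(0.18), 18 / 82)
  expect_equal(risk_to_odds(0.5), 1)
  expect_equal(risk_to_odds(0), 0)
  expect_error(risk_to_odds(1), class = "ocm_error_odds")
  expect_equal(odds_to_risk(36 / 82), 36 / 118)
  expect_equal(odds_to_risk(1), 0.5)
  expect_equal(odds_to_risk(0), 0)
  expect_error(odds_to_risk(-0.1), "non-negative")
  r <- seq(0.001, 0.999, by = 0.001)
  expect_equal(odds_to_risk(risk_to_odds(r)), r, tolerance = 1e-14)
})

test_that("odds-ratio lookup returns tabulated cells and rejects unknown levels", {
  expect_equal(lookup_odds_ratio(ors, "congestive_heart_failure", horizon = 10), 3.82)
  expect_equal(lookup_odds_ratio(ors, "congestive_heart_failure", horizon = 15), 3.67)
  expect_equal(lookup_odds_ratio(ors, "angina", cholesterol = "both", horizon = 15), 4.09)
  expect_equal(lookup_odds_ratio(ors, "diabetes", level = "0-5", horizon = 10), 1.00)
  # comorbidities without cholesterol variants ignore the modifier state
  expect_equal(lookup_odds_ratio(ors, "hypertension", cholesterol = "both", horizon = 10),
               lookup_odds_ratio(ors, "hypertension", horizon = 10))
  expect_error(lookup_odds_ratio(ors, "gout", horizon = 10), class = "ocm_error_lookup")
  expect_error(lookup_odds_ratio(ors, "asthma", level = "crippling", horizon = 10),
               "valid levels")
})

test_that("table invariants are asserted on load", {
  expect_true(all(ors$odds_ratio >= 1))
  # corrupt copies are rejected
  df <- as.data.frame(ors)
  df$odds_ratio[1] <- 0.9
  p <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df, p)
  expect_error(load_odds_ratio_table(p), ">= 1")
  df <- as.data.frame(ors)
  # break none <= high_total <= low_hdl <= both for angina at 10 years
  df$odds_ratio[df$comorbidity == "angina" & df$cholesterol == "both" & df$horizon == 10] <- 1.6
  readr::write_csv(df, p)
  expect_error(load_odds_ratio_table(p), "monotone")
})

test_that("combined odds ratio multiplies per-comorbidity ratios", {
  expect_equal(combined_odds_ratio(ocm_profile(65, smoking = "current", angina = TRUE),
                                   ors, horizon = 10), 2.0 * 1.55)
  expect_equal(combined_odds_ratio(ocm_profile(65), ors, horizon = 10), 1.0)
  expect_equal(combined_odds_ratio(
    ocm_profile(65, congestive_heart_failure = TRUE, stroke = "infarction"),
    ors, horizon = 15), 3.67 * 2.85)
})

test_that("cholesterol modifiers apply to every cholesterol-sensitive comorbidity independently", {
  p <- ocm_profile(65, angina = TRUE, peripheral_vascular_disease = TRUE,
                   hypertension = TRUE, high_total_cholesterol = TRUE)
  fac <- odds_ratio_factors(p, ors, horizon = 10)
  expect_equal(fac$odds_ratio[fac$comorbidity == "angina"], 1.84)
  expect_equal(fac$odds_ratio[fac$comorbidity == "peripheral_vascular_disease"], 2.00)
  expect_equal(fac$odds_ratio[fac$comorbidity == "hypertension"], 1.29) # unmodified
  # cholesterol flags alone contribute no factor
  expect_equal(nrow(odds_ratio_factors(
    ocm_profile(65, high_total_cholesterol = TRUE, low_hdl = TRUE), ors, 10)), 0)
})

test_that("adjusted risk reproduces the worked legend examples after whole-percent rounding", {
  cases <- list(
    list(profile = ocm_profile(65, smoking = "current"), pct = 31, risk = 36 / 118),
    list(profile = ocm_profile(65, angina = TRUE), pct = 25, risk = NA),
    list(profile = ocm_profile(65, angina = TRUE, smoking = "current"), pct = 40, risk = NA),
    list(profile = ocm_profile(65, congestive_heart_failure = TRUE), pct = 46,
         risk = odds_to_risk(0.18 / 0.82 * 3.82))
  )
  for (cs in cases) {
    est <- adjusted_risk(0.18, cs$profile, ors, horizon = 10)
    expect_equal(percent_round(est$adjusted_risk), cs$pct)
    if (!is.na(cs$risk)) expect_equal(est$adjusted_risk, cs$risk, tolerance = 1e-12)
    expect_equal(est$adjusted_risk,
                 odds_to_risk(risk_to_odds(est$baseline_risk) * est$combined_odds_ratio))
    expect_equal(est$combined_odds_ratio, prod(est$contributing_factors$odds_ratio))
  }
})

test_that("adjustment is monotone, bounded and exact for the empty profile", {
  expect_identical(adjusted_risk(0.18, ocm_profile(65), ors, 10)$adjusted_risk, 0.18)
  # adding a comorbidity with OR > 1 never lowers the estimate
  base_est <- adjusted_risk(0.3, ocm_profile(70, angina = TRUE), ors, 10)$adjusted_risk
  more_est <- adjusted_risk(0.3, ocm_profile(70, angina = TRUE, smoking = "former"),
                            ors, 10)$adjusted_risk
  expect_gt(more_est, base_est)
  # a tabulated no-op (diabetes 0-5 years, pulmonary embolus) leaves it unchanged
  noop <- adjusted_risk(0.3, ocm_profile(70, diabetes = "0-5", pulmonary_embolus = TRUE),
                        ors, 10)
  expect_identical(noop$adjusted_risk, 0.3)
  expect_equal(nrow(noop$contributing_factors), 2) # recorded, even at OR 1.00
  # increasing baseline increases the adjusted risk
  p <- ocm_profile(70, congestive_heart_failure = TRUE)
  expect_true(adjusted_risk(0.4, p, ors, 10)$adjusted_risk >
                adjusted_risk(0.3, p, ors, 10)$adjusted_risk)
  # extreme odds-ratio products stay below 1
  sick <- ocm_profile(75, congestive_heart_failure = TRUE, heart_attack = TRUE,
                      stroke = "infarction", smoking = "current", diabetes = ">20",
                      peripheral_vascular_disease = TRUE, low_hdl = TRUE,
                      high_total_cholesterol = TRUE, asthma = "severe")
  est <- adjusted_risk(0.40, sick, ors, 10)
  expect_gt(est$combined_odds_ratio, 100)
  expect_lt(est$adjusted_risk, 1)
  expect_error(adjusted_risk(1, ocm_profile(65), ors, 10), "\\[0, 1\\)")
})

test_that("patient schema validation itemizes violations and fills absent columns", {
  ok <- validate_patients(data.frame(age = 65, angina = 1, smoking = "never"))
  expect_true(all(ocmrisk:::profile_fields() %in% names(ok)))
  expect_identical(ok$angina, TRUE)
  err <- tryCatch(
    validate_patients(data.frame(age = 65, smoking = "maybe", asthma = "bad")),
    error = function(e) conditionMessage(e)
  )
  expect_match(err, "smoking")
  expect_match(err, "asthma")
  expect_error(ocm_profile(65, arthritis = TRUE), "unknown profile field")
})

test_that("cohort prediction appends risks per horizon and matches the single-patient path", {
  pts <- dplyr::bind_rows(ocm_profile(65, smoking = "current"),
                          ocm_profile(72, congestive_heart_failure = TRUE),
                          ocm_profile(58))
  out <- predict_ocm(pts)
  expect_equal(nrow(out), 3)
  expect_true(all(c("baseline_risk_10y", "adjusted_risk_10y",
                    "baseline_risk_15y", "adjusted_risk_15y") %in% names(out)))
  for (i in 1:3) {
    est <- adjusted_risk(out$baseline_risk_10y[i], pts[i, ], ors, 10)
    expect_equal(out$adjusted_risk_10y[i], est$adjusted_risk)
  }
  expect_identical(out$baseline_risk_10y[3], 0.11) # age 58, adjusted table
})
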
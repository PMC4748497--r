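test_that("concordance is 1 for perfect ranking and 0.5 for constant predictions", {
  d <- data.frame(predicted_risk = c(0.9, 0.5, 0.1),
                  followup_years = c(1, 2, 3), event = c(1, 1, 1))
  expect_equal(harrells_c(d), 1)
  d$predicted_risk <- 0.4
  expect_equal(harrells_c(d), 0.5)
})

test_that("a hand cohort with censoring matches exhaustive pair enumeration", {
  d <- data.frame(
    predicted_risk = c(0.8, 0.6, 0.7, 0.65, 0.4),
    followup_years = c(2, 5, 4, 9, 7),
    event = c(TRUE, TRUE, FALSE, TRUE, FALSE)
  )
  # 6 usable pairs (censored records usable only after an event), one of them
  # discordant: the year-5 event carries a lower prediction than the year-9 one
  expect_equal(harrells_c(d),
               oracle_concordance(d$followup_years, d$event, d$predicted_risk))
  expect_equal(harrells_c(d), 5 / 6) # frozen from hand enumeration
})

test_that("concordance agrees exactly with the oracle on random censored cohorts", {
  set.seed(7)
  for (rep in 1:40) {
    d <- random_cohort(n = sample(5:30, 1), censor_frac = runif(1, 0, 0.5),
                       tie_preds = rep %% 2 == 0)
    expected <- oracle_concordance(d$followup_years, d$event, d$predicted_risk)
    if (is.na(expected)) {
      expect_error(harrells_c(d), class = "ocm_error_concordance")
    } else {
      expect_identical(harrells_c(d), expected)
    }
  }
})

test_that("concordance is rank-based: monotone transforms preserve it, reversal flips it", {
  set.seed(11)
  d <- random_cohort(25, censor_frac = 0.3)
  c0 <- harrells_c(d)
  d2 <- d; d2$predicted_risk <- plogis(5 * d$predicted_risk - 1)
  expect_identical(harrells_c(d2), c0)
  d3 <- d; d3$predicted_risk <- 1 - d$predicted_risk
  expect_equal(harrells_c(d3), 1 - c0)
})

test_that("concordance refuses degenerate cohorts", {
  expect_error(harrells_c(data.frame(predicted_risk = 0.5, followup_years = 1, event = 1)),
               "at least 2")
  expect_error(harrells_c(data.frame(predicted_risk = c(.1, .2),
                                     followup_years = c(1, 2), event = c(0, 0))),
               class = "ocm_error_concordance")
  # only tied follow-up times: no usable pairs
  expect_error(harrells_c(data.frame(predicted_risk = c(.1, .2),
                                     followup_years = c(3, 3), event = c(1, 1))),
               class = "ocm_error_concordance")
})

test_that("Kaplan-Meier event probability matches hand product-limit arithmetic", {
  # events at 2, 4, 8; censored at 6; S(10) = 4/5 * 3/4 * 1/2 = 0.3
  expect_equal(km_event_probability(c(2, 4, 6, 8, 12), c(1, 1, 0, 1, 0), 10), 0.7)
  expect_equal(km_event_probability(rep(3, 10), rep(1, 10), 10), 1)
  expect_equal(km_event_probability(rep(12, 10), rep(0, 10), 10), 0)
  # without censoring before the horizon it is the empirical proportion
  set.seed(3)
  t <- rexp(200, 0.08)
  expect_equal(km_event_probability(t, rep(1, 200), 10), mean(t <= 10))
})

test_that("calibration bins partition the cohort with non-decreasing mean predictions", {
  set.seed(5)
  d <- data.frame(predicted_risk = runif(100),
                  followup_years = rexp(100, 0.1), event = TRUE)
  cal <- calibration_curve(d, horizon = 10, n_bins = 10)
  expect_equal(cal$n, rep(10L, 10))            # deciles of 100 distinct values
  expect_equal(sum(cal$n), attr(cal, "n_total"))
  expect_false(is.unsorted(cal$mean_predicted))
  # constant predictions collapse to one bin equal to the overall estimate
  d$predicted_risk <- 0.3
  cal1 <- calibration_curve(d, horizon = 10, n_bins = 10)
  expect_equal(nrow(cal1), 1)
  expect_equal(cal1$observed,
               km_event_probability(d$followup_years, rep(TRUE, 100), 10))
  expect_error(calibration_curve(d, horizon = 10, n_bins = 1), "at least 2")
})

test_that("event recoding treats prostate-cancer deaths as censoring by default", {
  code <- c(0, 1, 2, 1)
  expect_identical(recode_events(code), c(FALSE, TRUE, FALSE, TRUE))
  expect_identical(recode_events(code, pc_deaths = "event"), c(FALSE, TRUE, TRUE, TRUE))
  expect_error(recode_events(c(0, 3)), "event_code")
})

test_that("validate_cohort bundles discrimination and calibration per horizon", {
  set.seed(9)
  coh <- generate_cohort(cohort_spec(2000, seed = 9))
  sim <- simulate_outcomes(coh, seed = 10, censor_horizon = 18)
  val <- validate_cohort(sim, horizons = c(10, 15))
  g <- glance(val)
  expect_equal(g$horizon, c(10, 15))
  expect_true(all(g$c_index > 0.5))
  td <- tidy(val)
  expect_true(all(c("mean_predicted", "observed", "horizon") %in% names(td)))
  expect_s3_class(autoplot(val), "ggplot")
  expect_s3_class(autoplot(val$calibration[["10"]]), "ggplot")
})
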
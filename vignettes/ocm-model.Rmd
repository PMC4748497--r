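---
title: "Other-cause mortality in localized prostate cancer: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Other-cause mortality in localized prostate cancer: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocmrisk)
```

## The problem

Treatment choice in localized prostate cancer hinges on whether the patient
will live long enough for a slow-growing tumor to kill him. Guideline advice
to "adjust the life table by clinical judgment" is neither reproducible nor
validated, and general comorbidity indices were not built for this decision.
`ocmrisk` implements a pragmatic alternative: an age-specific baseline risk
of death from other causes, taken from an actuarial life table and shifted
to reflect the selected health of men presenting for prostate-cancer
treatment, multiplied on the odds scale by comorbidity-specific odds ratios
derived from life-insurance data.

## The model, step by step

**Baseline.** The packaged life table holds, for ages 50–75, the probability
of death within 10 and within 15 years, in the raw actuarial column and in
an adjusted column equal to the raw risk three years of age younger. The
shift is a configuration constant (`ocm_model(shift_years = )`, default 3):
it is a point estimate of the difference between treated-cohort survival and
population survival, and users may wish to vary it. With the default, the
printed adjusted column is used verbatim (it also covers ages 50–52, whose
raw sources lie below the printed range); any other shift rebuilds the
baseline from the raw column and therefore starts at `50 + shift_years`.

**Comorbidity adjustment.** A risk `p` becomes odds `p/(1-p)`; each
comorbidity present multiplies the odds by its tabulated ratio; the product
maps back through `o/(1+o)`. Two readings of the odds-ratio step are
possible in principle (multiply the odds, or rescale the risk); the package
follows the operational arithmetic of the published worked example — 18%
→ odds 18:82, smoker ×2.0 → 36:82 → 31% — which multiplies the odds
numerator. Points worth making explicit:

* Cholesterol (total > 270 mg/dL, HDL < 20 mg/dL) is a *modifier*, never a
  standalone factor. It selects the row variant for each of the six
  cholesterol-sensitive comorbidities the patient has, independently — a
  patient with high total cholesterol, angina and peripheral vascular
  disease receives the cholesterol-modified ratio for both conditions.
* Smoking status and diabetes duration are mutually exclusive single-level
  categoricals; "former smoker" carries 1.50 at both horizons as tabulated.
* Two tabulated entries are exactly 1.00 (pulmonary embolus without
  cholesterol modifiers; diabetes of 0–5 years). They are applied literally
  and appear in the audit trail (`odds_ratio_factors()`) as recorded no-ops.
* The product is not capped. Multiplying many cardiovascular odds ratios
  double-counts shared risk and will overestimate at the extreme; we keep
  the arithmetic literal because at such risks (say 90% vs 95% at 15 years)
  the distinction no longer changes clinical decisions. Co-occurring heart
  attack and angina likewise multiply unconditionally.

**Competing-risk step.** Untreated (conservative-management)
prostate-cancer mortality tables are indexed by risk group and age band.
Risk group assignment uses clinical stage and collapsed Gleason grade (≤6,
7, ≥8) only; PSA is excluded because it adds little prognostic information
once a localized cancer is diagnosed and staged. The conditional
prostate-cancer mortality is `(1 − p_ocm) × p_untreated`. The source
describing this step does not write the formula out; we use the
independence-style product — the simplest reading of "taking into account
the probability that he would not die of another cause" — and document it
prominently. Finer actuarial decompositions (e.g. integrating cause-specific
hazards over time) are out of scope.

**Gleason regrading.** Tables built on cohorts graded in the 1990s predate
the grading shift of the early 2000s. Assuming a fraction `f` (default
0.25, configurable — net upgrading of about 19% from Gleason 6, with a third
of upgrades beyond 7, is approximately equivalent in risk to 25% upgraded to
Gleason 7) of the historical low-risk group would be Gleason 7 today, with
upgraded patients carrying the average of the low and intermediate risks,
the historical low risk is the mixture
`r_low_old = (1-f) r_low_new + f (r_low_old + r_int_old)/2`, solved for the
contemporary value `r_low_new`. Intermediate and high groups pass through
unchanged: only the Gleason-6 upgrade is described by the underlying
regrading study, and we do not invent a corresponding outflow adjustment.
A table for which the deconvolved low risk would be negative is rejected as
inconsistent with the assumed fraction.

## Validation machinery

**Concordance.** `harrells_c()` uses exact pair semantics, stated because
implementations differ: a pair is usable only if the member with strictly
shorter follow-up had an event; pairs with tied follow-up times are
unusable; tied predictions on usable pairs count 1/2. The O(n²) pair scan is
in C++; the test suite checks it against an exhaustive enumeration oracle
on random censored cohorts, and checks the rank-invariance properties
(monotone transforms preserve c; reversing predictions maps c to 1 − c).
No confidence intervals are attached.

**Calibration.** `calibration_curve()` bins patients into quantiles of
predicted risk (default 10 bins; ties go to the lower bin, so large tie
groups can merge bins) and compares the per-bin mean prediction with the
Kaplan–Meier event probability at the horizon (via `survival::survfit`).
Kaplan–Meier rather than the raw event fraction keeps the observed axis
honest under censoring before the horizon.

**Event coding.** Deaths from prostate cancer censor the other-cause
endpoint by default (cause-specific convention); `recode_events(...,
pc_deaths = "event")` switches to an all-cause reading.

## The synthetic cohort generator

Because the registry cohort used to validate the original model is not
public, the package ships a generator that emulates its structure, and
outcomes are simulated *from the model's own predictions*, closing the loop
model → data → validation: a correct implementation must calibrate on the
identity against its own simulations, and any systematic per-bin gap
signals an arithmetic defect rather than model misfit.

* **Ages**: truncated normal on the life-table range 50–75, floored to
  completed years, with location 77.57 and scale 13 chosen so the integer
  ages have median exactly 67. The reference cohort's quartiles (60, 73)
  are more left-skewed than any truncated normal allows; ours come out at
  (62, 71), which we accept rather than leave the prescribed family.
* **Comorbidities**: independent Bernoulli draws at registry prevalences —
  hypertension 0.43, diabetes 0.18, angina 0.13, heart attack 0.11,
  congestive heart failure 0.072, stroke 0.05. Stroke subtype is not
  reported there; 80% of strokes are assigned
  infarction/thrombosis/embolism (the clinical ischemic share) and 20%
  hemorrhage. Diabetic duration defaults to the 0–5-year band, and
  smoking, cholesterol and the remaining model comorbidities default to
  absent, mirroring a cohort that recorded only a subset of the model's
  inputs; all prevalences are configurable. A `correlation` hook accepts a
  post-processing function for users who want correlated draws — real
  comorbidities are correlated, and independence understates the spread of
  combined odds ratios.
* **Outcomes**: each patient's event time has a piecewise-constant hazard
  on [0, 10) and [10, ∞) solved from the predicted 10- and 15-year risks,
  so the cumulative event probability matches both predictions exactly;
  the second hazard continues beyond 15 years. Administrative censoring
  defaults to 18 years, keeping both endpoints estimable while resembling a
  cohort with roughly 13 years of median follow-up. The hypertension
  prevalence reflects the reference cohort's liberal self-report
  definition, which is broader than the model's ≥160/≥90 mmHg criterion —
  the generator makes no attempt to reproduce that cohort's resulting
  miscalibration, only its structure.

What passing the synthetic checks does **not** show: performance on real
patients. The generator's outcomes are drawn from the model itself, so
calibration on the identity verifies the implementation, not the model's
truth; discrimination in the synthetic cohort reflects the spread of
predictions under independent comorbidities at the stated prevalences, not
a clinical c-index.

## Numerical and interface choices

* Display rounding is whole-percent, half **up** (0.305 → 31%); internal
  arithmetic is full precision, and the narrative report is rendered from
  the rounded structured fields so the two can never disagree.
* Non-integer ages are floored to completed years. Ages above the table
  maximum clamp to it with a warning (the oldest patients' risks are
  already in the range where overestimation is clinically irrelevant);
  ages below the minimum raise an error — the asymmetry is deliberate, and
  risks below the printed range are never extrapolated.
* Life tables are validated on load: contiguous integer ages (a missing
  row names the gap), risks in [0, 1] and non-decreasing in age; the
  odds-ratio table must have all ratios ≥ 1 and monotone cholesterol
  variants. These guards exist to catch transcription errors in
  user-supplied tables.
* Deterministic seeding throughout the generator; identical specs and
  seeds give byte-identical cohorts.

The test suite exercises the validation loop at a cohort size of 20,000
(decile calibration within 0.03 of the identity at both horizons, c-index
above 0.60) and checks the simulator's generating probabilities with
10,000 replicate draws per case; the exhaustive concordance oracle runs on
100 random cohorts of up to 30 patients.

## Known limitations

* The comorbidity set is fixed and shallow (no severity within congestive
  heart failure, no angina classes, no comorbidities outside the list);
  clinical judgment must supply what the model cannot.
* The multiplicative-odds combination ignores comorbidity interactions and
  will overestimate for the sickest, oldest patients.
* The packaged untreated-mortality table is a synthetic example shipped so
  the competing-risk pipeline is runnable and testable; users should
  substitute published conservative-management estimates for their
  population (file format: `risk_group, age_band, horizon, risk`).
* The life table covers ages 50–75; the model is silent below 50.
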
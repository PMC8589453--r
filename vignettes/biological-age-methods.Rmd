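---
title: "Estimating biological age from clinical biomarkers: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating biological age from clinical biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinage)
```

## The problem

Individuals of the same chronological age (CA) can differ markedly in
physiological condition. Biological age (BA) summarises a person's state
through biomarkers that drift with age — creatinine, blood pressure,
albumin, HbA1c and similar routine clinical measurements — and is a better
mortality predictor than CA alone. Chronic metabolic disease is a natural
application: people with diabetes show BA well above their CA, and the gap
(delta age, `dAge = BA - CA`) predicts subsequent mortality.

`clinage` implements the estimators and the full surrounding workflow:
biomarker screening and preprocessing, per-gender calibration on controls,
out-of-sample BA for disease groups, delta-age and age-ratio statistics,
and survival validation. Because the cohorts this methodology is usually
applied to are restricted (clinic registries, trial data), the package
ships a synthetic cohort generator that reproduces exactly the statistical
structure the estimators assume, so every stage can be exercised and
power-checked end to end.

## The estimators

### Klemera–Doubal method (KDM1)

The KDM framework assumes, for each biomarker \(j\),

\[ x_j = q_j + k_j \, \mathrm{BA} + \varepsilon_j, \qquad
   \varepsilon_j \sim N(0, s_j^2), \]

and for each individual \(\mathrm{BA} = \mathrm{CA} + R_{AB}\) with
\(R_{AB}\) zero-mean noise. Calibration regresses each biomarker on CA in
controls, per gender, giving the triple \((q_j, k_j, s_j)\) with \(s_j\)
the residual root mean square (denominator \(n - 2\); at calibration sizes
in the thousands the denominator choice is negligible, but it is fixed so
closed-form test oracles are exact). Prediction inverts the biomarker laws
and combines them by precision weighting:

\[ \widehat{\mathrm{BA}} \;=\;
   \frac{\sum_j (x_j - q_j)\, k_j / s_j^2}{\sum_j k_j^2 / s_j^2}, \]

which is the minimiser of
\(\sum_j \big((x_j - q_j - k_j\,\mathrm{BA})/s_j\big)^2\). This is the
"method 1" variant: CA itself is **not** an input to the estimate, and the
CA-augmented variant (with its \(s_{BA}^2\) characteristic) is out of
scope. The estimator is invariant to rescaling any biomarker together with
its triple, and under the generative assumptions the regression of
\(\widehat{\mathrm{BA}}\) on CA has slope 1.

### Multiple linear regression (MLR)

MLR regresses CA directly on the panel,
\(\mathrm{BA}_i = b_0 + \sum_j b_j x_{ji}\), per gender. Because it is a
forward regression onto noisy predictors it shrinks predictions toward the
mean training age; on noisy data its BA-on-CA slope is strictly below
KDM1's. The package treats this regression-to-the-mean contrast as a
structural property and tests it, since it is the standard argument for
preferring KDM over MLR.

### Phenotypic age

Phenotypic age (PhAge) is a fixed-coefficient formula over nine blood
markers plus CA (albumin g/L, creatinine µmol/L, glucose mmol/L, CRP
mg/dL with an `ln(CRP)` term, lymphocyte %, MCV fL, RDW %, ALP U/L, WBC
10³ cells/µL):

\[ \mathrm{PhAge} = 141.50 + \frac{\ln\!\big[-0.0053 \ln(1 - xb)\big]}{0.09165}. \]

Two readings of the linear predictor \(xb\) are implemented:

* **`levine-sign`** (default): additive intercept \(-19.907\) with a
  signed albumin term \(-0.0336 \cdot \mathrm{albumin}\), following the
  original coefficient signs.
* **`as-printed`**: a literal reading in which the leading term is the
  *product* \(-19.907 \times 0.0336 \times \mathrm{albumin}\). This makes
  \(xb\) scale-degenerate and is retained only behind a flag for fidelity
  audits.

Two further quirks of the printed form are deliberate and documented
rather than "fixed". First, the outer expression applies
\(\ln(1 - xb)\) to the linear predictor directly, omitting the
Gompertz-CDF mortality step of the original derivation, and its constants
(0.0053, 0.09165) differ slightly from the original publication's
(0.00553, 0.090165); the package evaluates the formula as printed.
Second, that omission narrows the domain: the formula needs
\(0 < xb < 1\), which realistic population marker values do not satisfy.
Out-of-domain subjects raise a per-subject error naming the offending
term (or map to `NA` under `on_domain_error = "na"`). A numerical
consequence worth recording: the analytic fixed point
\(\mathrm{PhAge} = 141.50\) requires \(1 - xb = e^{-1/0.0053} \approx
10^{-82}\), below the resolution of double-precision arithmetic near 1,
so the fixed point is unattainable numerically; the test suite checks the
outer form by inversion instead.

## Preprocessing and screening

Biomarker preparation follows the order **Box–Cox → standardise →
winsorise → gender-adjust**, matching the narrative order of the original
workflow; the fitted `transform_spec` records all parameters so the order
is auditable. Where the narrative is ambiguous about whether gender
adjustment preceded winsorisation, this package fixes the order as above
and freezes it in the recipe object. Choices that the source workflow
leaves unstated, fixed here once:

* **Box–Cox λ**: maximum profile likelihood over \([-5, 5]\), coarse grid
  (step 0.1) then golden-section refinement to tolerance \(10^{-4}\).
  Markers containing non-positive values skip the transform entirely
  (the policy adopted for a diastolic pressure column with one zero
  reading) rather than being shifted.
* **Winsor limits**: (1 %, 99 %), configurable. Bounds are inverse-ECDF
  order statistics of the input, which makes winsorisation exactly
  idempotent (interpolated quantile types are not).
* **Selection threshold**: univariate OLS of each biomarker on CA;
  selected when the slope p-value is below 0.05.
* **Redundancy**: pairs with \(|r| > 0.75\) (strictly) are flagged,
  advisory only; the drop-the-weaker-marker policy is applied only on
  request.
* **CA-paradox flag**: univariate \(R^2 > 0.32\) flags a marker as so
  collinear with CA that it mostly restates calendar age. Flagged markers
  are retained, mirroring the treatment of creatinine in the source
  analyses.
* **Leakage control**: the recipe is fitted on training controls only and
  frozen before being applied to held-out controls or disease groups.

## The synthetic cohort generator

The generator *is* the package's study condition, not a tuning knob. Its
defaults encode: 2000 subjects, CA uniform on 20–80 years (uniform because
only the age bounds are specified by the source setting, and uniform ages
maximise leverage for the calibration regressions), equal gender split,
individual BA noise `s_ba = 5` years, and a disease-group BA shift of
+12 years — the magnitude reported for type-2 diabetes. Eight biomarkers
follow linear-in-BA laws whose slope signs match the screening-table
directions (creatinine, blood pressures, urea nitrogen, cholesterol,
pulse and HbA1c rise with age; albumin falls); the magnitudes are free
parameters of the emulation, chosen once so that each marker carries a
clearly detectable age signal and the eight-marker KDM estimate has a
residual sd of roughly 3.7 years. Missingness is completely at random
(the source workflow simply excludes incomplete rows, so MCAR suffices);
outliers multiply a random cell by a configurable factor from {3, 5},
giving winsorisation something to shrink. Survival times are exponential
with hazard \(h_0 \exp(\beta \cdot \mathrm{dAge})\) and administrative
censoring — the simplest law consistent with fitting a Cox model.

Two honest limitations of this emulation. First, because all markers share
the single BA driver with strong signal, their mutual correlations exceed
the 0.75 redundancy cutoff by construction; the pipeline's advisory flag
fires on synthetic data even though no marker is dropped. Real panels are
far noisier (univariate \(R^2\) of 0.03–0.36) and do not trip the flag.
Second, the phenotypic-age panel defaults are calibrated to the printed
formula's \((0,1)\) domain for \(xb\) rather than to population reference
ranges — with realistic marker levels the printed formula is undefined for
everyone, so a generator emulating the formula's domain cannot
simultaneously emulate reference intervals. Passing tests therefore
demonstrate correctness of the estimators under their stated assumptions,
not performance on any real cohort; the cohort-specific magnitudes of the
source analyses (mean shifts of 12.02 or 16.61 years, HR 1.23, median
dAge 9.85) require restricted data and are explicitly not reproduced.

## Cohort preparation

* **Exclusions**: controls with HbA1c at or above 5.7 % (strictly-below
  cutoff, so undiagnosed prediabetes is excluded), rows with missing
  required values, rows outside 20–80 years. The rules are conjunctive,
  so final membership is order-independent; a per-rule log supports
  CONSORT-style reporting.
* **Matching**: the source setting specifies only "matched by age and
  gender". Implemented as greedy nearest-age matching within gender,
  without replacement, caliper 2 years by default, seeded random
  tie-breaks — simple, auditable, and testable against a brute-force
  assignment oracle on small fixtures.
* **Split**: two-thirds training, stratified by gender so both per-gender
  models are always trainable.

## Survival validation

`fit_dage_cox()` wraps a Cox proportional-hazards fit (Efron tie
handling — the accuracy-preferred convention; oracle fixtures use untied
times so the choice is not load-bearing) with Wald confidence intervals on
the log-hazard scale, iteration cap 100. Delta age enters either
continuously (HR per year) or dichotomized at the in-sample median with
the "high" arm defined as `dAge >= median`. The full validation loop —
generate survival from a positive per-year log-HR, refit with the Cox
stage — recovers the generative hazard ratio; the parameter-recovery tests
fit on the generator's true delta age, since fitting on *estimated* delta
age attenuates the hazard ratio toward 1 (classical measurement-error
bias), a distinction users should keep in mind when interpreting real
analyses.

## Problem sizes and determinism

The shipped checks use cohorts of 1000–5000 subjects and 100-seed
replicate loops, sizes at which every stochastic assertion has a
comfortable margin (for example, the held-out mean delta age at
n ≈ 667 has standard error ≈ 0.24 years against a ±0.5-year band).
Every simulation entry point takes an explicit seed and restores the
caller's RNG state, so identical configurations reproduce byte-identical
cohorts, masks included.

## Worked example

```{r example}
cfg <- cohort_config(n_subjects = 800, seed = 1)
cohort <- rbind(simulate_controls(cfg),
                simulate_disease(cohort_config(n_subjects = 400,
                                               group_shift = 12, seed = 2)))
run <- suppressWarnings(  # advisory redundancy flag; see above
  run_pipeline(cohort, panel = "kdm8", preprocess = FALSE, seed = 3))
run
```

The control-vs-disease mean delta-age difference recovers the injected
12-year shift with a vanishing rank-sum p-value. The recovered difference
slightly exceeds 12 because the HbA1c exclusion rule removes controls in
the upper tail of the BA distribution (their simulated A1c crosses the
5.7 % cutoff), truncating the control group downward — the same selection
effect the cutoff produces in real cohorts, and the reason the source
workflow's control A1c distribution is lower than population surveys'.
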
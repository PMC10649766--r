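---
title: "Inverse-problem dose planning for head and neck CTA: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse-problem dose planning for head and neck CTA: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctadose)
```

## The problem

Head and neck CT angiography needs the attenuation measured in the
left artery — the CTA number, on the Hounsfield scale — to fall in a
narrow window (roughly 350–450, target 400) for the vessels to read
well. The achieved CTA number depends jointly on patient physiology
(age, body surface area, heart rate, cardiac output) and on the
acquisition protocol (tube voltage, injected contrast-media volume,
delayed trigger timing). The only factor the operator freely controls
per patient is the contrast-media volume, so the clinically useful
question is inverse: *given this patient and this protocol, what dose
drives the predicted CTA number to 400?*

`ctadose` answers that in two stages: fit a semi-empirical regression
of the CTA number on all seven factors, then invert the fitted model in
the dose factor.

## Stage 1: the 29-term semi-empirical model

Every factor and the response are first min-max normalized onto
$[-1, +1]$:

$$x^* = \frac{x - (x_{max}+x_{min})/2}{(x_{max}-x_{min})/2},$$

where $x_{min}, x_{max}$ are the factor's extreme readings over the
derivation cohort. The response is the observed CTA number divided by
400, passed through the same transform (packaged bounds 0.61–2.17).
Normalization puts all factors on a common dimensionless scale, so the
fitted coefficients are directly comparable as effect sizes; the
transform is affine and exactly invertible, which Stage 2 relies on.

The normalized response $v_8$ is modelled as first-order in each
normalized factor $v_1 \dots v_7$ with all 21 pairwise
cross-interactions and a constant:

$$v_8 = \sum_{j=1}^{7} a_j v_j \;+\; \sum_{j<k} a_{jk}\, v_j v_k \;+\; a_{29}.$$

Triple and higher interactions are deliberately excluded; their
residual influence is absorbed by the constant term. The 29
coefficients minimize the squared-error loss
$\Phi = \lVert V a - y \rVert^2$, whose unique minimizer for a
full-column-rank design is the normal-equations solution
$a = (V^\top V)^{-1} V^\top y$. The package solves the same problem by
QR factorization — identical minimizer, better conditioning — and keeps
the explicit dense-inverse solve only as an independent oracle in the
test suite. Rank deficiency is an error rather than a pseudo-inverse
fallback, because interpreting and inverting the model assumes a unique
coefficient vector. Fits report $\Phi$, the coefficient of
determination ("variance"), and the observed–predicted correlation
$R$; with the constant column present these satisfy
$\text{variance} = R^2$, which the tests assert to $10^{-9}$.

## Stage 2: exact dose inversion

For a new patient the six non-dose factors are fixed at their
normalized readings, and the dose factor $v_6$ is set to $+1$ and $-1$
— the raw dose extremes of the training cohort (17 and 75 c.c. for the
packaged model). Because the model is affine in $v_6$ once the other
factors are fixed, its dose response is exactly the straight line
through the two extreme predictions, so the dose attaining the target
solves

$$\frac{CM_{expect}-CM_{min}}{CM_{max}-CM_{min}} =
  \frac{400 - v_8(v_6{=}-1)}{v_8(v_6{=}+1)-v_8(v_6{=}-1)},$$

operating on raw (denormalized) CTA numbers. Re-predicting at the
recommended dose returns the target to machine precision; the test
suite enforces $10^{-6}$ CTA units over whole simulated cohorts.

Two policy decisions surround the closed form:

- **Clipping.** The model's linearity in dose is only trusted inside
  the range it was trained on, so a recommendation outside
  $[CM_{min}, CM_{max}]$ is by default clamped into it and flagged
  `clipped`; `clip = FALSE` (CLI `--allow-extrapolation`) disables
  this. A target not bracketed by the two extreme predictions is
  additionally flagged `achievable = FALSE`.
- **Zero sensitivity.** Coefficient sets can make a particular
  patient's predicted CTA number (nearly) independent of dose; the
  planner raises an explicit error for that patient rather than
  dividing by a vanishing slope, and batch planning collects such
  errors per patient instead of aborting.

A negative dose slope (more contrast lowering the prediction) is
allowed and surfaced via the two extreme predictions, since some
covariate combinations produce it through the interaction terms.

## Verification: the agreement statistic

Model verification uses the per-patient agreement
$AT = |actual - predicted| / actual$, reported in percent, with cohort
mean, sample (n−1) standard deviation, and a histogram in 2%-wide
lower-inclusive bins anchored at 0. The absolute value is a
documented choice: the statistic is used as a nonnegative deviation
measure throughout.

## The synthetic cohort generator

Clinical tables of this kind are privacy-restricted, so every pipeline
stage is exercised on synthetic cohorts. The generator's defaults are
frozen to the published cohort summaries:

- **Marginals.** Each factor is drawn from a normal distribution
  truncated to its published range, with the published mean and SD
  (derivation cohort: age 56 ± 13.3 yr on 24–90, tube voltage
  100 ± 19 kVp on 70–140, BSA 1.75 ± 0.20 m² on 1.27–2.70, HR
  72.1 ± 12.8 on 45–139, CO 6.32 ± 1.06 L/min on 4.18–11.11, CM
  36.7 ± 11.5 c.c. on 17–75, DTT 3.08 ± 0.53 s on 2.00–5.13).
  Truncated-normal sampling uses the inverse-CDF method, so a seed
  fully determines the cohort.
- **Tube voltage** is snapped to the clinical step set
  {70, 80, 100, 120, 140} kVp after the draw (verification spec:
  {100, 120}); CT scanners offer discrete settings, and the published
  extremes are exactly such steps. A continuous mode is available by
  omitting `levels` from the spec.
- **Responses.** The true normalized response is the packaged 29-term
  reference formula evaluated at the patient's normalized factors;
  Gaussian noise with SD 0.084 is added on the normalized scale, and
  the observed CTA number is recovered by the inverse transform × 400.
  The default 0.084 is calibrated so the expected residual sum of
  squares at n = 450 matches the published fit-loss scale
  ($\sqrt{3.184/450} \approx 0.084$) — a calibration from printed
  summary statistics, not from patient data.
- **Response-range conditioning.** Independent marginals occasionally
  combine into factor vectors whose true response falls outside the
  empirical response scale (about 11% of draws), including a small
  fraction that would imply non-positive CTA numbers. Observed cohorts
  cannot contain such patients — their response bounds *are* empirical
  ranges — so `simulate_cohort()` rejection-samples until every
  patient's true normalized response lies in $[-1, +1]$. The induced
  marginal shift is negligible (age mean 55.94 vs the configured 56 at
  n = 20000).
- **Verification cohorts** sample from their own published marginals
  but are normalized and evaluated under the derivation cohort's
  scaling bounds, exactly as a trained model would be applied to new
  patients; the two range sets are nearly but not exactly nested,
  which is why out-of-range normalization is a warning (or, in strict
  mode, an error) rather than silent.

What the generator does *not* emulate: any correlation structure among
factors (heart rate and cardiac output are physiologically coupled;
the spec format accepts only independent marginals), measurement error
in the factor readings themselves, scanner drift over time, and the
published tables' internal inconsistencies (one source table reports a
normalized-response SD of 1.524, impossible for values confined to
$[-1,1]$ with the reported mean; treated as a typesetting artifact).
Passing tests therefore demonstrate that the *pipeline* is correct and
well-calibrated under realistic marginals and noise — not that the
published coefficient values are the right model for any particular
clinic's patients.

## Numerical choices and degenerate inputs

- Scaling bounds with $x_{max} \le x_{min}$, constant factors in a
  derivation cohort, non-finite or non-positive readings, and design
  matrices with fewer than 29 rows are all hard errors with the
  offending factor, column, or row named.
- The BSA convenience helper uses the Mosteller form
  $\sqrt{H \cdot W / 3600}$ (height in cm, weight in kg); the
  radical-free variant produces values far outside the plausible adult
  range.
- Model JSON is written with 17 significant digits, making
  serialize → parse bit-exact for doubles; files whose term-label
  order differs from the canonical 29-term order are rejected rather
  than reordered.
- Dose-plan equality checks use an absolute tolerance of $10^{-6}$ raw
  CTA units; the zero-sensitivity guard triggers below $10^{-9}$ CTA
  units of spread between the two extreme predictions.

## Problem sizes

The test suite and acceptance checks run the generator at the
published cohort sizes (450 derivation, 112 verification, 65 dose
planning) and, for convergence properties, up to n = 4500 with 8–20
replicates — sizes chosen to make Monte-Carlo checks decisive while
keeping the whole suite interactive (a few seconds).

## Worked session

```{r example}
spec   <- table1_cohort_spec(n = 450, seed = 7)
cohort <- simulate_cohort(spec)
model  <- fit_ipa(cohort, bounds = spec$bounds)
model

patient <- data.frame(age = 60, kvp = 100, bsa = 1.8,
                      hr = 72, co = 6.3, dtt = 3.1)
plan_dose(patient, table3_model())
```

The fitted $\Phi$ lands near $n \sigma^2 \approx 3.2$ as designed, and
the recommended 30.8 c.c. reproduces the 400 target exactly on
re-prediction.

## Known limitations

- The model is purely statistical: no pharmacokinetics of bolus
  transit, no dose–image-quality tradeoff beyond the single CTA-number
  target, and no uncertainty quantification on coefficients or
  recommended doses (the pipeline's published form reports point
  estimates only).
- Single-target inversion only; constrained variants (e.g. minimal
  dose subject to CTA ∈ [350, 450]) are out of scope.
- Recommendations outside the trained dose range carry no evidence
  from the model; they are clipped and flagged by default, and
  extrapolation is at the user's risk.
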
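---
title: "HbA1c variability and kidney-function decline: models, generator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HbA1c variability and kidney-function decline: models, generator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

In people living with type 2 diabetes, kidney function — measured as the
estimated glomerular filtration rate (eGFR, mL/min/1.73 m²) — declines
over years. Identifying who is declining fast matters clinically: a mean
eGFR slope of −5 mL/min/1.73 m²/yr or steeper ("rapid decline") carries
a large excess hazard of kidney failure, and a slope difference of 0.75
mL/min/1.73 m²/yr is commonly treated as the minimal important
difference (MID).

The exposure of interest is visit-to-visit HbA1c variability summarised
by the **HbA1c variability score (HVS)**: the percentage of successive
HbA1c measurements that differ from the previous one by at least 0.5
percentage points (NGSP; ≈5.5 mmol/mol). HVS is banded at 20% intervals
into five categories, with HVS ≤ 20% as the reference; the bands above
the reference are left-open, so HVS = 20% is category 1 and HVS = 80.01%
is category 5.

`glycovar` implements the complete analysis pipeline from raw
longitudinal EMR-style tables to weighted effect estimates, together
with a synthetic-data generator that plants known truths so that every
stage is testable without access to any private database.

# Pipeline

1. **Cohort construction.** Eligibility requires ≥5 outpatient visits
   over ≥1 year (from the first visit with an HbA1c measurement — the
   index date — to the last visit with an HbA1c or creatinine
   measurement), ≥3 serum creatinine measurements, and baseline eGFR
   ≥ 15; adults only. Baseline covariates are captured from 30 days
   before the index date to one year after, taking the measurement
   nearest the index (ties resolved toward the earlier record).
   Exclusion reasons are assigned in a fixed order (`no_index`,
   `not_adult`, `min_visits`, `min_span`, `min_scr`,
   `insufficient_hba1c`, `no_baseline_egfr`, `min_baseline_egfr`) so the
   log is deterministic; the source protocol does not define an order,
   and the two extra reasons (`not_adult`, `insufficient_hba1c`) make
   implicit preconditions explicit.
2. **Derived measures.** eGFR from the 2009 CKD-EPI creatinine equation
   with the race coefficient fixed at 1 (the cohort modelled is
   Chinese) and age advanced to the measurement date; creatinine
   reported in µmol/L is divided by 88.4 first. Same-day duplicate labs
   are averaged before any series computation. HVS uses all HbA1c
   measures from index to end of follow-up (the alternative — a
   baseline-window HVS — would not reflect long-term variability).
   Time-weighted average (TWA) HbA1c is the integral of the
   piecewise-linear interpolant divided by the spanned time. The
   per-subject eGFR slope is ordinary least squares of eGFR on years;
   analyses require ≥3 in-window points.
3. **Entropy balancing.** For each HVS category `g`, weights
   `w_i ∝ exp(λ_g·c(x_i))` (normalised to mean 1 within the category)
   minimise KL divergence from uniform weights subject to *exact* first
   moment constraints on nine covariates: age, sex, baseline eGFR <60
   flag, hypertension-or-ASCVD flag, ever use of insulin / statins /
   ARB-ACEI, TWA HbA1c, and adherence (visits/yr). All five categories,
   including the reference, are balanced to the pooled (full-sample)
   moments: the analysis is symmetric "across HVS categories", and a
   pooled target is the symmetric reading; balancing to the reference
   category's moments is retained as an option. The convex dual is
   solved per category by damped Newton with step halving (tolerance
   1e-8 on the maximum standardized moment violation, ≤200 iterations).
   Covariates are standardized internally, which makes the weights
   invariant to affine rescaling. First moments only: binary covariates
   are then matched exactly, and no moment order is prescribed by the
   source.
4. **Outcome models.** (a) Rapid decline (slope ≤ −5, inclusive) is
   modelled by weighted logistic regression on category indicators;
   confidence intervals use the robust sandwich variance, treating the
   estimated balancing weights as probability weights (the model-based
   variance is available as an option; the source does not state its
   estimator). (b) Slope differences come from a linear mixed model of
   eGFR on category, time (years) and category×time, with a random
   intercept and random slope per subject (unstructured 2×2
   covariance). Each subject's log-likelihood contribution is
   multiplied by its weight; estimation is maximum likelihood (not
   REML) so weighted likelihoods remain comparable across fixed-effect
   specifications. β and the residual variance are profiled
   analytically; the 2-parameter-plus-correlation relative covariance
   is optimised by Nelder–Mead in compiled code. If the random-effect
   correlation hits the boundary (|ρ| > 0.995) the model is refit with
   a diagonal covariance and a warning. Standard errors are model-based
   Wald. The interaction coefficients are the slope differences and are
   compared in absolute value against the MID (0.75).
5. **Subgroups and sensitivity analyses.** Both models are refit within
   strata of sex, age (<60 vs ≥60), ever insulin use, and baseline eGFR
   (<60 vs ≥60); balancing weights are re-estimated within each stratum
   (whether the source did so is unstated; re-estimation is the
   internally consistent choice, and the stratifying covariate drops
   out of the constraints automatically because it is constant
   in-stratum). The sensitivity suite re-runs the pipeline with
   windowed slopes (2/3/4/5 years), excluding subjects whose last HbA1c
   and creatinine are ≥90 days apart, balancing on baseline HbA1c
   instead of TWA HbA1c, excluding baseline eGFR <30, and excluding
   SGLT2-inhibitor/GLP-1-receptor-agonist users.

# The synthetic-data generator

The generator emits the five EMR tables (subjects, visits, labs,
medications, diagnoses) from a stated world calibrated once to the
published cohort's marginals:

* **Follow-up** is Uniform(1.5, 7.9) years, which reproduces the
  published median 4.7 and IQR [3.1, 6.3] exactly.
* **Visits** follow a Poisson process with per-subject lognormal rates
  (median 1.9/yr, log-SD 0.542 → IQR ≈ [1.3, 2.7]). The first visit is
  the index visit and always carries an HbA1c; other visits miss the
  HbA1c or creatinine measurement with configurable probabilities, and
  a knob creates subjects whose creatinine series stops ≥120 days
  before the last visit, so the ≥90-day "unparallel measures"
  sensitivity exclusion is exercisable.
* **HVS bands.** Each subject draws a latent band from the published
  occupancy (506/585/661/444/201 of 2397). Within a band with per-pair
  jump probability `p` (band midpoints 0.1 … 0.9 by default), each
  successive HbA1c change is at/above the 0.5% threshold with
  probability `p` (0.5 + half-normal(σ = 0.4) when it jumps, uniform on
  [0, 0.5) otherwise), mean-reverting toward a personal level. Because
  a short Bernoulli series frequently realises an HVS outside its
  latent band — which would both distort band occupancy and attenuate
  any planted per-band effect — the cohort generator redraws the jump
  indicator sequence until the realised HVS lands in the assigned band
  (rejection sampling; the realised HVS equals the jump-indicator mean
  exactly, so this is cheap). Bands that a very short series cannot
  realise at all (two pairs can only give 0/50/100%) keep the nearest
  draw; such subjects are rare among eligible cohorts.
* **Personal HbA1c levels** are gamma-shaped (right-skewed, skewness
  ≈1.4) around per-band means 6.8–8.6% with per-band SDs 0.4–1.3%,
  matching the published per-category TWA IQRs. The skew matters:
  diabetic HbA1c has a long right tail, and with a symmetric light tail
  the pooled balance target would sit outside the realised support of
  the extreme categories, making exact balancing infeasible.
* **Kidney function.** Each subject's latent trajectory is
  `baseline + slope·t` plus Gaussian measurement noise (SD 4 by
  default), floored above 1; creatinine is obtained by closed-form
  inversion of CKD-EPI at the attained age, so recomputing eGFR
  downstream round-trips exactly. Per-band mean slopes default to
  (−0.33, −0.58, −0.83, −1.26, −2.16) mL/min/1.73 m²/yr — the
  published reference decline and the published extra declines for the
  top two bands; the two middle offsets are not numerically reported in
  the available text and are set to monotone intermediates below the
  MID. Between-subject slope SD within a band defaults to 1.5: real
  cohorts show wide slope heterogeneity, and an interior random-slope
  variance keeps the mixed model well-specified and produces a
  realistic (if conservative) share of rapid decliners.
* **Covariates** (hypertension, ASCVD, insulin, statins, ARB/ACEI, CCB,
  SGLT2i/GLP-1RA) follow the published per-category prevalences, e.g.
  insulin use rising from 20.6% to 55.2% across bands, so balancing has
  genuine confounding to remove.

A faster subject-level simulator (`simulate_analysis_cohort()`) skips
the lab-series layer and emits the derived cohort row directly, with a
planted log-odds model for the rapid-decline indicator and optional
longitudinal eGFR. Its `confounded` switch selects between the
Table-1-style gradients and a category-independent covariate world at
the pooled marginals.

# What a green test does and does not establish

The parameter-recovery studies plant the published effect sizes as
simulation truth and require the full pipeline to recover them. For the
slope targets this runs the entire EMR path (tables → cohort → balance
→ weighted mixed model) under the confounded world; recovery there
validates the machinery end to end, but note that because the generator
ties slopes to the HVS band alone, weighting changes the variance, not
the estimand — a green recovery does not prove that balancing removes
outcome confounding (that is what the null-calibration and
balance-exactness suites address from the other side).

For the odds-ratio targets, the recovery world is deliberately
*unconfounded*: with the published covariate gradients, exact pooled
balancing must tilt the reference category's TWA-HbA1c mean by ≈1.3
within-category SDs, which collapses the effective sample size to a few
percent and makes the weighted OR both noisy (per-replicate SD
0.25–0.55) and Jensen-biased far beyond any usable tolerance — in any
light-tailed world, not just ours. The confounded world is exercised
instead by the balance-exactness criterion (post-weighting max |SMD|
< 1e-6 across all nine covariates and five categories). OR targets are
summarised across replicates by the geometric mean, the natural
averaging scale for ratio estimates. This is also an honest caveat for
the real analysis this package mirrors: with Table-1-like gradients and
small extreme categories, exact-balance weights are extreme, and
model-based intervals on the weighted scale should be read cautiously.

# Numerical choices

* CKD-EPI inversion is closed-form (the curve is piecewise power and
  strictly decreasing); the tests check it against independent
  root-finding and a 1e-6 round-trip.
* HVS comparisons use an absolute tolerance of 1e-9 at the 0.5%
  threshold so that decimal HbA1c values stored in binary floats
  compare as intended; the threshold itself is inclusive.
* Entropy-balancing Newton steps are damped by halving until the dual
  objective does not increase; infeasible targets (outside a category's
  convex hull, or a constant covariate off target) are reported as
  errors naming the covariate and category rather than returned as
  degenerate weights.
* The mixed-model deviance is profiled: given the relative
  random-effects covariance Ψ, both β (weighted GLS) and σ² have closed
  forms, leaving a 3-parameter search (log relative SDs, correlation on
  a tanh scale) done by Nelder–Mead with a restart; per-subject
  cross-products are precomputed once in compiled code, so a fit costs
  milliseconds per thousand subjects. The noise-free limit is handled
  by flooring the profiled σ² at 1e-12.
* All randomness flows through R's seeded generator; identical configs
  give byte-identical tables, and the written manifest omits the
  timestamp so reruns compare equal at the byte level.

# Known limitations

* The generator's visit rate is category-independent, so the published
  adherence gradient (1.9 → 1.6 visits/yr) appears only in the
  subject-level simulator, not in the full EMR world.
* Rapid-decline prevalence in the default full world (≈0.5–7% by band)
  is below the ≈10% reference probability used for the planted-outcome
  studies; raising the slope heterogeneity to match would make the
  slope-recovery targets unmeasurably noisy, so the two worlds are kept
  separate and documented.
* ICD-10 comorbidity capture is prefix matching against configurable
  lists (the source's appendix code lists are unavailable); free-text
  diagnosis parsing is out of scope.
* Model-based Wald intervals for the weighted mixed model do not
  account for the estimation of the balancing weights; under heavy
  tilting they are anti-conservative. The null-calibration suite checks
  coverage only in the moderate-weight world.
* Death and kidney-replacement-therapy outcomes are not modelled.
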
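# glycovar

Visit-to-visit HbA1c variability and kidney-function decline in type 2
diabetes: a tested, reusable analysis pipeline with a synthetic-EMR
generator.

## The problem

Clinicians caring for people with type 2 diabetes want to know who is
losing kidney function fast. Kidney function is tracked as the estimated
glomerular filtration rate (eGFR, mL/min/1.73 m², from the 2009 CKD-EPI
creatinine equation); a per-subject **eGFR slope** of −5 mL/min/1.73
m²/yr or steeper defines *rapid decline*, and a slope difference of
0.75 mL/min/1.73 m²/yr is the minimal important difference (MID).

The exposure is the **HbA1c variability score (HVS)** — the percentage
of successive HbA1c measurements differing by ≥0.5% (NGSP; ≈5.5
mmol/mol) from the previous one — banded into five 20%-wide categories
with HVS ≤ 20% as the reference. The analysis asks: do people in higher
HVS bands decline faster, after balancing covariates across bands?

The statistical core:

* **Entropy balancing**: per-category weights `w_i ∝ exp(λ_g·c(x_i))`
  minimising KL divergence from uniform weights subject to *exact*
  first-moment constraints on nine covariates (age, sex, baseline eGFR
  <60, hypertension/ASCVD, ever insulin / statin / ARB-ACEI,
  time-weighted average HbA1c, adherence), solved per category in the
  convex dual by damped Newton.
* **Weighted logistic regression** of rapid decline on HVS category
  (sandwich variance) → odds ratios vs the reference band.
* **Weighted linear mixed model** of eGFR on category × time with
  random intercept and slope per subject, subject-level likelihood
  weights, profiled ML → the reference mean slope (the `time`
  coefficient) and four interaction coefficients = slope differences,
  compared against the MID.

Because the motivating cohort is not publicly available, the package
ships a synthetic-EMR generator (`sim_config()` / `simulate_cohort()`)
whose defaults encode the published marginals (category occupancy
506/585/661/444/201, median follow-up 4.7 y, 1.9 visits/yr, Table-1
covariate gradients, per-band slopes −0.33 … −2.16) so every stage is
testable against planted ground truth. See the methods vignette
(`vignettes/glycovar-methods.Rmd`) for the model assumptions, generator
design and limitations.

## Worked example

```r
library(glycovar)

cfg <- sim_config(n_subjects = 2400, follow_up_years = 5,
                  follow_up_spread = 1, visit_rate = 4,
                  visit_rate_logsd = 0, p_miss_hba1c = 0,
                  p_miss_scr = 0, p_unparallel = 0,
                  true_slope_sd = 0, seed = 20221111)
raw    <- simulate_cohort(cfg)          # five EMR tables
cohort <- build_cohort(raw)             # eligibility + derived measures
bal    <- entropy_balance(cohort, cohort$hvs_category)
max(abs(bal$smd_after))                 # exact balance
#> [1] 1.999841e-09

mx <- fit_weighted_mixed_slopes(
  attr(cohort, "egfr_long"),
  setNames(cohort$hvs_category, cohort$subject_id),
  setNames(bal$weights, cohort$subject_id))
mx[, c("term", "scale", "estimate", "ci_low", "ci_high", "exceeds_mid")]
#>              term            scale   estimate     ci_low     ci_high exceeds_mid
#> 1 reference_slope            slope -0.3484338 -0.3983157 -0.2985519          NA
#> 2   hvs_cat2:time slope_difference -0.2332621 -0.3012563 -0.1652679       FALSE
#> 3   hvs_cat3:time slope_difference -0.4748190 -0.5417018 -0.4079361       FALSE
#> 4   hvs_cat4:time slope_difference -0.8960797 -0.9693564 -0.8228029        TRUE
#> 5   hvs_cat5:time slope_difference -1.8595438 -1.9511740 -1.7679136        TRUE
```

Reading the output: the reference band declines by 0.35 mL/min/1.73
m²/yr on average (planted truth 0.33); bands 4 and 5 decline by an
extra 0.90 and 1.86 mL/min/1.73 m²/yr (planted truths 0.93 and 1.83),
both beyond the MID of 0.75, while bands 2–3 (planted 0.25 and 0.50)
stay below it — the pattern the pipeline is designed to detect. This
run turns off within-band slope heterogeneity (`true_slope_sd = 0`) so
a single replicate is informative; with the realistic default
(`true_slope_sd = 1.5`) each contrast carries Monte-Carlo noise of
roughly ±0.25 and conclusions need replicate averaging, which is what
the acceptance report does.

The full pipeline (simulate → cohort → balance → both models → Table-1
summary → manifest) is one call, or one shell command:

```r
res <- run_pipeline(cfg, out_dir = "out")   # writes CSV/JSON bundle
res$table1[1:4, 1:4]
```

```sh
Rscript inst/cli/glycovar run --config cfg.json --seed 1 --out out/
```

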
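Package: glycovar
Title: Visit-to-Visit HbA1c Variability and Kidney Function Decline
Version: 0.1.0
Authors@R:
    person("WECODe", "Reanalysis Team", email = "glycovar@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline linking the HbA1c variability score (HVS) to
    kidney-function decline in longitudinal outpatient records: a synthetic
    EMR-table generator with known ground truth, cohort eligibility and
    baseline capture, derived biomarkers (CKD-EPI eGFR, HVS and its 20%
    categories, time-weighted average HbA1c, per-subject eGFR slopes and the
    rapid-decline rule), entropy-balancing weights that exactly match
    covariate first moments across HVS categories, and weighted outcome
    models (sandwich-variance logistic regression for rapid decline; a
    profiled weighted-likelihood linear mixed model with category-by-time
    interaction for eGFR-slope differences), plus subgroup and sensitivity
    suites and a Table-1-style descriptive report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
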
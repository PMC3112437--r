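Package: cariesrisk
Title: Additive Odds-Ratio Risk Scoring and Screening-Test Validation for
    Adolescent Dental Caries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a multifactorial additive risk-score instrument for
    population-based dental caries screening in adolescents (per-factor
    weights equal to odds ratio minus one, summed and thresholded into
    Low/Moderate/High risk using WHO mean-DMFT benchmark cut-offs), the
    DMFT (decayed, missing, filled permanent teeth) gold standard, and the
    machinery to validate the instrument against that standard: per-stratum
    two-by-two tables, sensitivity, specificity, predictive values and
    prevalence with Wilson or Wald confidence intervals, multi-year
    summaries, and Cronbach's alpha.  Also provides the instrument
    construction procedure (least-squares variable screening followed by
    logistic-regression odds ratios) and a seeded synthetic cohort
    generator with prevalence-calibrated intercepts for end-to-end
    parameter-recovery experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
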
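# cariesrisk

Additive odds-ratio risk scoring for adolescent dental caries, and the
validation of that score as a population screening test against the DMFT
gold standard.

## What this is for

School nurses, health educators and physicians see adolescents far more
often than dentists do. A demographic risk-score instrument lets them
flag likely future caries risk without a dental examination and refer
accordingly. This package implements such an instrument and everything
needed to validate one:

* **The risk model.** Ten demographic factors (fluoridation exposure,
  environmental smoke, race, age, locale, tobacco use, BMI, insurance
  status, sex, sealants). Each at-risk level carries weight
  `OR − 1` (its odds ratio against the factor's referent, minus one, so
  the "no risk" column is zero); an individual's score is the sum over
  factors. Scores are banded with the WHO mean-DMFT benchmarks
  repurposed as cut-offs — Low ≤ 2.6, Moderate 2.7–4.4, High ≥ 4.5 — and
  dichotomized for screening: positive iff score ≥ 2.7.
* **The gold standard.** The DMFT index (decayed + missing + filled
  permanent teeth); DMFT ≥ 1 is *with disease*.
* **Validation.** Per-stratum 2×2 tables, sensitivity `TP/(TP+FN)`,
  specificity `TN/(TN+FP)`, predictive values `TP/(TP+FP)` and
  `TN/(TN+FN)`, prevalence, Wilson/Wald confidence intervals,
  cross-year unweighted means, Cronbach's alpha, and an audit of
  printed marginals against cell sums.
* **Instrument construction.** OLS screening of candidate variables
  against DMFT severity, logistic-regression odds ratios with
  VIF diagnostics, and assembly into a scoring model.
* **Synthetic cohorts.** A seeded generator with
  prevalence-calibrated logistic disease and a DMFT severity model, plus
  an end-to-end parameter-recovery experiment.

A transcription of the six published Nevada academic-year 2×2 tables
(2002/2003–2007/2008, 51,295 screenings) ships as a fixture; the
individual-level surveillance records were never deposited, which is
what the synthetic generator stands in for. The instrument's original
fitted odds ratios were published only as a figure, so the packaged
default model configuration is explicitly illustrative.

## Worked example

```r
library(cariesrisk)

tabs <- nevada_tables()          # the six published per-year 2x2 tables
summarize_years(tabs)
#> Screening validity by stratum (integer %, wilson CIs at level 0.95):
#>    stratum sensitivity specificity pvp pvn prevalence
#>  2002/2003          75          85  91  63         67
#>  2003/2004          80          79  90  62         71
#>  2004/2005          76          78  85  67         62
#>  2005/2006          82          80  89  70         65
#>  2006/2007          85          90  93  78         62
#>  2007/2008          78          73  85  63         66
#>       mean          79          81  89  67         66
#> Total screened: 51295
```

Reading the bottom row: across the six years the instrument detected on
average 79% of adolescents who truly had caries experience (sensitivity)
and correctly cleared 81% of those who did not (specificity); 89% of
positive screens were true cases (high, because prevalence itself
averaged 66%), while a negative screen was right 67% of the time. The
per-year integers above reproduce the published summary table wherever
that table agrees with its own counts; two published cells that
contradict their counts (one predictive value, one prevalence) are
asserted at the recomputed value, documented in the fixture header.

Scoring and screening an individual profile:

```r
m <- read_model_config(system.file("extdata", "model_default.yaml",
                                   package = "cariesrisk"))
p <- c(fluoridation = "nonfluoridated", smoke_exposure = "exposed",
       race = "hispanic", age = "15-16", locale = "metro",
       tobacco_use = "nonuser", bmi = "normal", insurance = "uninsured",
       sex = "male", sealants = "absent")
s <- risk_score(p, m)
s                                  # 4.0
as.character(classify_risk(s, m))  # "Moderate"
as.character(dichotomize(classify_risk(s, m)))  # "positive"
```

End-to-end on synthetic data:

```r
cfg <- default_population_config(n_per_stratum = 5000, seed = 1)
r <- recovery_experiment(cfg)      # generate -> refit -> score -> validate
head(r$or_recovery)                # true vs estimated odds ratios
r$validity                         # per-stratum Se/Sp/PVP/PVN/prevalence
```

A command-line surface wrapping these functions (subcommands `score`,
`validate`, `develop`, `simulate`, `report`) is installed at
`system.file("cli", "cariesrisk.R", package = "cariesrisk")`.

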
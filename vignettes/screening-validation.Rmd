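---
title: "Additive odds-ratio risk scoring and its validation against the DMFT standard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Additive odds-ratio risk scoring and its validation against the DMFT standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cariesrisk)
```

## The screening problem

Dental caries in adolescents is common enough (prevalence well above 50%
in many US populations) that individual dental examination of every
student is impractical, while the people who see adolescents most often —
school nurses, health educators, physicians — are not dental
professionals. A population-based screening instrument lets them flag
likely future caries risk from demographic information alone and refer
accordingly. `cariesrisk` implements such an instrument, its gold
standard, and the machinery to ask the question that matters about any
screening test: how well does its positive/negative call agree with true
disease status?

## The risk model

The instrument is a flow-chart score over ten demographic factors
(exposure to fluoridated water, environmental smoke exposure, race, age,
locale, tobacco use, Body Mass Index, dental insurance status, sex, and
sealant application). Each factor level carries a weight

$$w_{\text{level}} = \mathrm{OR}_{\text{level}} - 1,$$

the level's fitted odds ratio against the factor's referent level minus
one, so the referent ("no risk") column is zeroed out and an individual's
total score is the sum of the weights of their observed levels:

$$S = \sum_{j=1}^{10} w_{j,\ \text{level}(j)} .$$

An all-referent profile scores exactly 0; each single at-risk level
raises the score by exactly its weight (the score is additive and
monotone by construction). The score is thresholded with the WHO
population mean-DMFT benchmarks repurposed as score cut-offs — Low
$\le 2.6$, Moderate $2.7\text{–}4.4$, High $\ge 4.5$ — and dichotomized
for screening: Moderate and High are collapsed to *test positive*, Low is
*test negative*, i.e. positive iff $S \ge 2.7$.

Two representation choices are worth stating:

* **The cut-off gap.** The printed bands leave the open interval
  (2.6, 2.7) unassigned, but fitted scores are continuous. The bands are
  implemented as half-open intervals $[0, 2.7)$, $[2.7, 4.5)$,
  $[4.5, \infty)$, which reproduces the printed label at every printed
  boundary value and assigns the gap to Low, consistent with "positive
  iff $S \ge 2.7$".
* **Protective factors.** The instrument's score column only *adds*
  risk. A level with fitted odds ratio below 1 (e.g. sealants present) is
  therefore re-expressed by re-choosing the factor's referent: all odds
  ratios are rescaled relative to the least-risky level, which becomes
  the new zero-weight referent. For a binary factor with protective odds
  ratio $r$ this puts weight $1/r - 1 \ge 0$ on the at-risk level. All
  stored weights are consequently non-negative.

The numeric odds ratios of the original Nevada instrument were published
only as a figure, without values recoverable from the text, so weights
are configuration-supplied. The packaged
`inst/extdata/model_default.yaml` ships *illustrative* odds ratios of
plausible magnitude — explicitly not the original fitted values — and
`read_model_config()` accepts any configuration in the same YAML dialect.

## The gold standard

Disease status is the DMFT index: the count of Decayed, Missing (due to
caries) and Filled permanent Teeth. DMFT $\ge 1$ is *with disease*,
DMFT $= 0$ is *without disease*. The component cap is 32 teeth (full
adult dentition) rather than 28, because 13–18-year-olds may have erupted
third molars. Records may carry either the three components or also a
precomputed total; if both are present and disagree the record is
rejected outright — fail-loud was preferred to silently trusting one
source. `who_severity()` applies the same Low/Moderate/High intervals to
a population mean DMFT, sharing the implementation with the score
classifier so the two can never drift apart.

## Validation metrics

For each stratum (academic year), pairing every subject's screening
result with their disease status yields a 2×2 table with cells TP, FP,
FN, TN, from which:

$$\mathrm{Se} = \frac{TP}{TP+FN},\quad
  \mathrm{Sp} = \frac{TN}{TN+FP},\quad
  \mathrm{PVP} = \frac{TP}{TP+FP},\quad
  \mathrm{PVN} = \frac{TN}{TN+FN},\quad
  \pi = \frac{TP+FN}{N}.$$

Predictive values depend on prevalence through Bayes' rule
($\mathrm{PVP}$ rises and $\mathrm{PVN}$ falls as $\pi$ rises); the test
suite checks this identity to $10^{-12}$ on the packaged tables and the
monotonicity over a grid. Cross-year summaries are **unweighted means of
per-year metrics**, not pooled-cell metrics — this is what reproduces the
published six-year averages exactly. Display values are rounded half-up
to integer percents, matching the published tables' granularity;
full-precision values are always carried alongside.

Each metric is an error, not an `NaN`, when its denominator is empty
(e.g. sensitivity in a disease-free stratum), and `summarize_years()`
propagates such errors with the stratum's name.

### Confidence intervals

The intervals printed alongside the original per-year percentages have
identical half-widths across years of very different size and cannot be
reproduced from any per-year $n$; their construction is not
identifiable, so the package does not attempt to match them. Instead
`proportion_ci()` provides the Wilson score interval (default; respects
$[0,1]$, never excludes the point estimate, behaves well at the extremes)
and the Wald interval (for comparison; truncated to $[0,1]$). The Wilson
implementation is verified against an independent numeric inversion of
the score test.

### Reliability

`cronbach_alpha()` implements the standard
$\alpha = \frac{k}{k-1}\bigl(1 - \sum_i s_i^2 / s_T^2\bigr)$ on an
observations-by-items matrix. The originally reported coefficient
(0.875) cannot be recomputed because the underlying data matrix — what
constituted "items" across the six years — was never published; the
operation is provided generically and validated against its closed-form
identities (identical items give 1; two items with correlation $r$ give
$2r/(1+r)$; independent noise gives $\approx 0$).

### Published-count fixture

`nevada_tables()` loads a bit-exact transcription of the six published
per-year 2×2 tables. Three transcription quirks are preserved and
documented in the fixture header rather than silently corrected:

* the 2004/2005 test-negative row total was printed as 4522 although its
  cells sum to 3112 (`validate_table_consistency()` flags exactly this);
* the 2002/2003 predictive value negative was printed as 64 although the
  cells give 62.78 → 63;
* the 2006/2007 prevalence was printed as 63 although the cells give
  62.46 → 62 (the same published row contains two further visibly
  corrupt entries).

Wherever a printed percentage disagrees with its own counts, the value
recomputed from the counts governs.

## Instrument construction

`screen_variables()` + `estimate_odds_ratios()` + `assemble_model()`
re-implement the two-stage construction procedure so it can be exercised
on synthetic cohorts:

1. **Screening** is an ordinary least-squares fit of the DMFT total (the
   severity measure) on all candidate factors simultaneously, retaining
   each variable whose single-deletion F-test has $p < \alpha$
   (default 0.05). The original description mentions a single screen
   against "prevalence and severity"; regressing the severity count —
   which carries the prevalence information in its zero/nonzero split —
   is the reading adopted here, and the logistic stage below handles
   prevalence proper. Under the null the retention rate is $\approx
   \alpha$ (checked by simulation).
2. **Odds ratios** come from a maximum-likelihood logistic fit of
   dichotomous disease status on the retained factors, indicator-coded
   against explicit referents, converging when the relative deviance
   change falls below $10^{-8}$. Complete or quasi-complete separation
   is a fit error with a diagnostic — no small-sample corrections (Firth,
   Haldane–Anscombe) are applied. On a single binary factor the fit is
   saturated, so the estimate must equal the closed-form cross-product
   ratio $ad/bc$; the tests require agreement to $10^{-9}$ and also
   compare against a direct grid-search likelihood maximizer.
   Multicollinearity is reported as per-design-column variance inflation
   factors ($1/(1-R^2_j)$, computed as the diagonal of the inverse
   design-correlation matrix) with a warning threshold of 10.
3. **Assembly** orders factors by descending standardized contribution
   ($|\hat\beta_j| \cdot \mathrm{sd}(x_j)$; a multi-level factor is
   ranked by its largest level), converts odds ratios to weights, and
   attaches the cut-offs.

## The synthetic cohort generator

No individual-level surveillance records were ever deposited, so the
generator stands in for them; its defaults are the study's stated
conditions, fixed once:

* six strata ("academic years") of 8,550 records — a 51,300-record
  cohort, matching the reported "over 51,000 screenings" across six
  years;
* target marginal disease prevalence 0.66, the reported six-year mean;
* ten factors mirroring the instrument's, drawn independently from
  illustrative marginals, with true odds ratios equal to the packaged
  default configuration;
* severity among the diseased: DMFT $= 1 + \mathrm{Poisson}(2.2)$,
  capped at 32 and split into decayed/missing/filled components in
  0.6/0.1/0.3 proportions, so the diseased-group mean (3.2) falls in the
  WHO Moderate band. No severity distribution was ever published; this
  is explicitly a stand-in.

Disease is Bernoulli with logistic probability
$\mathrm{logit}^{-1}(\beta_0 + \sum_j \beta_{j,\,\text{level}(j)})$.
The intercept $\beta_0$ is **calibrated**: `calibrate_intercept()`
computes the exact population-averaged probability by enumerating all
factor-level combinations under the independence assumption (3,072
combinations for the default ten factors) and solves for the root of
(average − target), which is strictly increasing in $\beta_0$, to an
achieved-prevalence tolerance of $10^{-6}$. DMFT and disease status are
generated jointly, so DMFT $\ge 1 \iff$ *with disease* holds exactly in
every cohort, not just in expectation.

Randomness uses a single root seed from which per-stratum seeds are
derived deterministically, so any stratum is reproducible in isolation
and identical seeds give bit-identical cohorts.

Factors are generated independently — the true joint distribution of the
ten factors in the original population is unknowable from what was
published, and no correlation structure is invented. This is the main
respect in which passing tests on synthetic data say nothing about real
data: under factor–factor correlation the marginal odds ratios, the
score distribution, and hence the operating point of the 2.7 threshold
would all shift. Equally, the generator's logistic disease model is the
same family the development stage fits, so parameter-recovery results
demonstrate correctness of the estimation machinery, not robustness to
model misspecification.

`recovery_experiment()` closes the loop: generate a cohort with known
coefficients, refit, assemble, score, validate per stratum, and report
true-versus-estimated odds ratios alongside the resulting
Se/Sp/PVP/PVN/prevalence. With all true coefficients zero the refit
odds ratios are $\approx 1$, every score sits far below 2.7, the
screening result is one-sided, and the experiment reports the
degeneracy explicitly instead of manufacturing undefined predictive
values.

## Numerical and design choices

* Scores are kept at full precision internally; only display rounds (to
  one decimal for scores, integer percents for metrics, both half-up —
  `round()`'s round-half-even would disagree with several published
  cells).
* Problem sizes in the test suite: odds-ratio recovery uses a single
  50,000-record stratum with balanced binary factors spanning odds
  ratios 1.2–5 (relative error below 5% at that size), calibration is
  checked at $n = 10^5$ against a ±0.01 band, and null-retention uses
  400 replicates of $n = 200$. These sizes were chosen as the smallest
  at which the corresponding claims are comfortably inside their noise
  bands.
* The records dialect is comma-delimited UTF-8 with a header and no
  auto-sniffing; duplicate record ids are rejected; strict mode aborts
  on the first invalid row, permissive mode skips and logs each one.

## Known limitations

* The shipped odds ratios are illustrative; conclusions about the real
  instrument's operating characteristics require its real weights.
* Cut-offs adopted from one population need not transfer to another (in
  a low-prevalence population nearly everyone may fall in the Low band).
* No ROC/AUC analysis or cut-off optimization is provided: the
  instrument fixes its cut-offs a priori, and the package validates, it
  does not re-tune.
* No DMFS (surface-level) or deciduous-tooth index; no longitudinal
  tracking of individuals (the surveillance design had none).

## A worked example

```{r example}
tabs <- nevada_tables()
summary <- summarize_years(tabs)
summary

# the one published marginal that disagrees with its own cells
fx <- attr(tabs, "fixture")
validate_table_consistency(
  tabs[["2004/2005"]],
  list(test_negative_total = fx$printed_test_negative_total[3]))
```
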
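# shared builders for small test fixtures

# binary factor with a single at-risk level
bf <- function(name, or, at_risk = "yes", ref = "no") {
  risk_factor(name, c(ref, at_risk), ref,
              stats::setNames(or, at_risk))
}

# two-factor toy model with default WHO cut-offs
toy_model <- function(or1 = 2.9, or2 = 1.8) {
  risk_model(list(bf("f1", or1), bf("f2", or2)))
}

# the six published per-year tables, loaded once per test file
nevada <- nevada_tables()

# round-trip helper: integer percents for one metric across the six years
nevada_pct <- function(metric_fun) {
  round_half_up(100 * vapply(nevada, metric_fun, numeric(1)))
}

# independent Wilson oracle: numeric inversion of the score test.
# the bounds are the two roots in p of (p_hat - p)^2 = z^2 p(1-p)/n,
# found by bisection rather than the closed form under test.
wilson_oracle <- function(p_hat, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  g <- function(p) (p_hat - p)^2 - z^2 * p * (1 - p) / n
  eps <- 1e-12
  lower <- if (p_hat == 0) 0 else
    uniroot(g, c(eps, p_hat), tol = 1e-12)$root
  upper <- if (p_hat == 1) 1 else
    uniroot(g, c(p_hat, 1 - eps), tol = 1e-12)$root
  c(lower = lower, upper = upper)
}

# small cohort with one binary exposure and logistic disease model
tiny_cohort <- function(n, or, p_exposed = 0.5, base_logodds = 0,
                        seed = 1) {
  set.seed(seed)
  x <- rbinom(n, 1, p_exposed)
  p <- plogis(base_logodds + log(or) * x)
  y <- rbinom(n, 1, p)
  data.frame(exposure = ifelse(x == 1, "yes", "no"),
             disease = factor(ifelse(y == 1, "with_disease",
                                     "without_disease"),
                              levels = c("without_disease", "with_disease")))
}

# expand a 2x2 of counts (a = exposed diseased, b = exposed healthy,
# c = unexposed diseased, d = unexposed healthy) into records
records_from_counts <- function(a, b, c, d) {
  data.frame(
    exposure = rep(c("yes", "yes", "no", "no"), c(a, b, c, d)),
    disease = factor(rep(c("with_disease", "without_disease",
                           "with_disease", "without_disease"),
                         c(a, b, c, d)),
                     levels = c("without_disease", "with_disease")))
}
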
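test_that("build_table routes every pair and conserves the count", {
  t <- build_table(c("positive", "negative"),
                   c("with_disease", "without_disease"))
  expect_equal(c(t$tp, t$fp, t$fn, t$tn), c(1, 0, 0, 1))
  t <- build_table(rep("positive", 3), rep("without_disease", 3))
  expect_equal(c(t$tp, t$fp, t$fn, t$tn), c(0, 3, 0, 0))
  # brute-force recount of 100 simulated pairs
  set.seed(42)
  res <- sample(c("positive", "negative"), 100, replace = TRUE)
  st <- sample(c("with_disease", "without_disease"), 100, replace = TRUE)
  t <- build_table(res, st)
  expect_equal(t$tp + t$fp + t$fn + t$tn, 100)
  expect_equal(t$tp, sum(res == "positive" & st == "with_disease"))
  expect_equal(t$tn, sum(res == "negative" & st == "without_disease"))
  expect_error(build_table(character(), character()), "no classification")
})

test_that("validity metrics match hand-computed published-year values", {
  t <- two_by_two(tp = 4098, fp = 407, fn = 1366, tn = 2304)
  expect_equal(sensitivity(t), 4098 / 5464)
  expect_equal(round(sensitivity(t), 4), 0.75)
  expect_equal(round(specificity(t), 4), 0.8499)
  expect_equal(round(pvp(t), 4), 0.9097)
  expect_equal(round(prevalence(t), 4), 0.6684)
  t2 <- two_by_two(tp = 4963, fp = 641, fn = 1090, tn = 2560)
  expect_equal(round(pvn(t2), 4), 0.7014)
})

test_that("metrics hit their boundary values and error on empty denominators", {
  expect_equal(sensitivity(two_by_two(5, 1, 0, 2)), 1)   # fn = 0
  expect_equal(specificity(two_by_two(5, 0, 1, 2)), 1)   # fp = 0
  expect_equal(pvp(two_by_two(5, 0, 1, 2)), 1)
  expect_equal(pvn(two_by_two(5, 1, 0, 2)), 1)
  expect_equal(prevalence(two_by_two(0, 3, 0, 4)), 0)
  expect_error(sensitivity(two_by_two(0, 3, 0, 4)), "undefined")
  expect_error(specificity(two_by_two(3, 0, 4, 0)), "undefined")
  expect_error(pvp(two_by_two(0, 0, 2, 2)), "undefined")
  expect_error(pvn(two_by_two(2, 2, 0, 0)), "undefined")
})

test_that("column scaling leaves sensitivity and specificity invariant", {
  t <- two_by_two(40, 10, 20, 30)
  for (k in c(2, 5, 10)) {
    expect_equal(sensitivity(two_by_two(40 * k, 10, 20 * k, 30)),
                 sensitivity(t))
    expect_equal(specificity(two_by_two(40, 10 * k, 20, 30 * k)),
                 specificity(t))
  }
})

test_that("Wilson interval matches an independent score-test inversion", {
  cases <- expand.grid(p = c(0.1, 0.5, 0.75, 0.9),
                       n = c(8, 120, 5464),
                       level = c(0.9, 0.95))
  for (i in seq_len(nrow(cases))) {
    got <- proportion_ci(cases$p[i], cases$n[i], cases$level[i], "wilson")
    want <- wilson_oracle(cases$p[i], cases$n[i], cases$level[i])
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("Wilson interval respects boundaries and shrinks with n", {
  for (p in c(0, 0.5, 1)) {
    for (n in c(1, 10, 1e4)) {
      ci <- proportion_ci(p, n)
      expect_true(ci["lower"] >= 0 && ci["upper"] <= 1)
      expect_true(ci["lower"] <= p && p <= ci["upper"])
    }
  }
  expect_equal(unname(proportion_ci(0, 50)["lower"]), 0)
  expect_equal(unname(proportion_ci(1, 50)["upper"]), 1)
  w <- vapply(c(10, 100, 1000), function(n)
    diff(proportion_ci(0.3, n)), numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("Wald interval equals the textbook formula, truncated to [0,1]", {
  z <- qnorm(0.975)
  ci <- proportion_ci(0.75, 5464, method = "wald")
  half <- z * sqrt(0.75 * 0.25 / 5464)
  expect_equal(unname(ci), c(0.75 - half, 0.75 + half))
  expect_equal(unname(proportion_ci(0.01, 10, method = "wald")["lower"]), 0)
  expect_error(proportion_ci(0.5, 10, level = 1.2), "level")
  expect_error(proportion_ci(0.5, 0), "n")
})

test_that("multi-year summary averages metrics, not pooled cells", {
  s <- summarize_years(nevada)
  # unweighted mean of per-year full-precision values
  per <- vapply(nevada, sensitivity, numeric(1))
  expect_equal(unname(s$means["sensitivity"]), mean(per))
  # a single table summarizes to itself
  s1 <- summarize_years(nevada[1])
  expect_equal(unname(s1$means["pvp"]), pvp(nevada[[1]]))
  expect_equal(s1$n_total, 8175)
})

test_that("undefined per-stratum metrics propagate with the stratum name", {
  degenerate <- two_by_two(0, 0, 2, 3, label = "yearX")
  expect_error(summarize_years(list(nevada[[1]], degenerate)), "yearX")
})

test_that("PVP and PVN follow Bayes' rule exactly on the published tables", {
  for (t in nevada) {
    se <- sensitivity(t); sp <- specificity(t); pi <- prevalence(t)
    expect_equal(pvp(t), se * pi / (se * pi + (1 - sp) * (1 - pi)),
                 tolerance = 1e-12)
    expect_equal(pvn(t), sp * (1 - pi) / (sp * (1 - pi) + (1 - se) * pi),
                 tolerance = 1e-12)
  }
})

test_that("PVP rises and PVN falls as prevalence increases", {
  for (se in c(0.6, 0.79, 0.95)) {
    for (sp in c(0.6, 0.81, 0.95)) {
      pi <- seq(0.05, 0.95, by = 0.05)
      ppv <- se * pi / (se * pi + (1 - sp) * (1 - pi))
      npv <- sp * (1 - pi) / (sp * (1 - pi) + (1 - se) * pi)
      expect_true(all(diff(ppv) > 0))
      expect_true(all(diff(npv) < 0))
      # cross-check through actual tables at two prevalences
      t_lo <- two_by_two(round(1e5 * se * 0.2), round(1e5 * (1 - sp) * 0.8),
                         round(1e5 * (1 - se) * 0.2), round(1e5 * sp * 0.8))
      t_hi <- two_by_two(round(1e5 * se * 0.8), round(1e5 * (1 - sp) * 0.2),
                         round(1e5 * (1 - se) * 0.8), round(1e5 * sp * 0.2))
      expect_gt(pvp(t_hi), pvp(t_lo))
      expect_lt(pvn(t_hi), pvn(t_lo))
    }
  }
})

test_that("Cronbach's alpha matches its closed-form identities", {
  # identical items: all unique variance vanishes
  x <- rnorm(50)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1)
  # two items with correlation r: Spearman-Brown 2r/(1+r)
  for (r in c(0.2, 0.5, 0.875)) {
    sigma <- matrix(c(1, r, r, 1), 2)
    ev <- eigen(sigma)
    rt <- ev$vectors %*% diag(sqrt(ev$values))
    set.seed(7)
    z0 <- scale(matrix(rnorm(4000), ncol = 2))
    z0 <- qr.Q(qr(z0)) * sqrt(nrow(z0) - 1)  # exactly uncorrelated columns
    z <- z0 %*% t(rt)                        # sample correlation exactly r
    expect_equal(cronbach_alpha(z), 2 * r / (1 + r), tolerance = 1e-10)
  }
  # independent noise: alpha near zero
  set.seed(123)
  noise <- matrix(rnorm(6 * 4000), ncol = 6)
  expect_lt(abs(cronbach_alpha(noise)), 0.05)
  expect_error(cronbach_alpha(matrix(1, 5, 3)), "variance")
  expect_error(cronbach_alpha(matrix(rnorm(4), 4, 1)), "2 items")
})

test_that("marginal audit flags exactly the published inconsistency", {
  fx <- attr(nevada, "fixture")
  for (i in seq_along(nevada)) {
    printed <- list(
      test_positive_total = fx$printed_test_positive_total[i],
      test_negative_total = fx$printed_test_negative_total[i],
      diseased_total = fx$printed_diseased_total[i],
      nondiseased_total = fx$printed_nondiseased_total[i],
      grand_total = fx$printed_grand_total[i])
    d <- validate_table_consistency(nevada[[i]], printed)
    if (fx$year[i] == "2004/2005") {
      expect_length(d, 1)
      expect_match(d, "test_negative_total.*4522.*3112")
    } else {
      expect_length(d, 0)
    }
  }
  # a fabricated wrong total is reported
  d <- validate_table_consistency(nevada[[1]], list(grand_total = 9999))
  expect_length(d, 1)
})
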
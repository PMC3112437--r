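test_that("variable screening retains what predicts severity", {
  set.seed(5)
  n <- 400
  rec <- data.frame(
    signal = sample(c("lo", "hi"), n, replace = TRUE),
    noise = sample(c("a", "b"), n, replace = TRUE))
  outcome <- ifelse(rec$signal == "hi", 4, 1) + rnorm(n, sd = 0.5)
  sc <- screen_variables(rec, outcome, c("signal", "noise"))
  expect_true(sc$retained[sc$variable == "signal"])
  expect_false(sc$retained[sc$variable == "noise"])
  expect_true(all(sc$p_value >= 0 & sc$p_value <= 1))
  # a predictor equal to the outcome is retained with p ~ 0
  rec2 <- data.frame(x = rnorm(50))
  sc2 <- screen_variables(rec2, rec2$x + rnorm(50, sd = 1e-3), "x")
  expect_true(sc2$retained)
  expect_lt(sc2$p_value, 1e-12)
  # alpha = 1 retains everything
  sc3 <- screen_variables(rec, outcome, c("signal", "noise"), alpha = 1)
  expect_true(all(sc3$retained))
})

test_that("screening type-I retention rate is close to alpha under the null", {
  set.seed(99)
  hits <- vapply(seq_len(400), function(i) {
    rec <- data.frame(x = sample(c("a", "b"), 200, replace = TRUE))
    screen_variables(rec, rnorm(200), "x")$retained
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 0.025)  # within 2.5 points of alpha
})

test_that("screening errors on degenerate designs", {
  rec <- data.frame(x = c("a", "a", "b", "b"), y = c("u", "u", "v", "v"))
  expect_error(screen_variables(rec, c(1, 2, 3, 4), c("x", "y")),
               "aliased|rank")
  expect_error(screen_variables(rec, rep(1, 4), "x"), "constant")
  expect_error(screen_variables(rec[1:3, ], c(1, 2, 3), c("x", "y")),
               "fewer observations|aliased|rank")
})

test_that("logistic odds ratio on one binary factor equals ad/bc", {
  rec <- records_from_counts(a = 40, b = 10, c = 20, d = 30)
  eff <- estimate_odds_ratios(rec, "disease", "exposure")
  expect_equal(eff$odds_ratio, 6.0, tolerance = 1e-9)
  # arbitrary counts: the saturated model reproduces the cross-product ratio
  rec2 <- records_from_counts(a = 17, b = 23, c = 11, d = 41)
  eff2 <- estimate_odds_ratios(rec2, "disease", "exposure")
  expect_equal(eff2$odds_ratio, (17 * 41) / (23 * 11), tolerance = 1e-9)
})

test_that("logistic fit matches a direct grid-search likelihood maximizer", {
  rec <- tiny_cohort(50000, or = 2.5, seed = 3)
  eff <- estimate_odds_ratios(rec, "disease", "exposure")
  # oracle: profile the 2-parameter log-likelihood on the collapsed 2x2
  a <- sum(rec$exposure == "yes" & rec$disease == "with_disease")
  b <- sum(rec$exposure == "yes" & rec$disease == "without_disease")
  c_ <- sum(rec$exposure == "no" & rec$disease == "with_disease")
  d <- sum(rec$exposure == "no" & rec$disease == "without_disease")
  ll <- function(b0, b1) {
    a * plogis(b0 + b1, log.p = TRUE) +
      b * plogis(b0 + b1, lower.tail = FALSE, log.p = TRUE) +
      c_ * plogis(b0, log.p = TRUE) +
      d * plogis(b0, lower.tail = FALSE, log.p = TRUE)
  }
  profile_ll <- function(b1) {            # maximize over b0 by refined grid
    g <- seq(-2, 2, length.out = 401)
    v <- NULL
    for (k in 1:3) {
      v <- vapply(g, function(b0) ll(b0, b1), numeric(1))
      i <- which.max(v)
      g <- seq(g[max(1, i - 1)], g[min(length(g), i + 1)],
               length.out = 401)
    }
    max(v)
  }
  g1 <- seq(log(1.5), log(4), length.out = 201)
  best <- g1[which.max(vapply(g1, profile_ll, numeric(1)))]
  g2 <- seq(best - 0.01, best + 0.01, length.out = 201)
  best <- g2[which.max(vapply(g2, profile_ll, numeric(1)))]
  expect_equal(log(eff$odds_ratio), best, tolerance = 1e-3)
  # and the estimate recovers the generating OR 2.5 at this n
  expect_gt(eff$odds_ratio, 2.3)
  expect_lt(eff$odds_ratio, 2.7)
})

test_that("separation and missing outcome classes are fit errors", {
  rec <- data.frame(
    exposure = rep(c("yes", "no"), each = 30),
    disease = factor(rep(c("with_disease", "without_disease"), each = 30),
                     levels = c("without_disease", "with_disease")))
  expect_error(estimate_odds_ratios(rec, "disease", "exposure"),
               "separation")
  rec$disease[] <- "with_disease"
  expect_error(estimate_odds_ratios(rec, "disease", "exposure"),
               "both outcome classes")
})

test_that("assembled model composes fitted odds ratios into weights", {
  set.seed(21)
  n <- 6000
  rec <- data.frame(
    strong = sample(c("no", "yes"), n, replace = TRUE),
    weak = sample(c("no", "yes"), n, replace = TRUE))
  p <- plogis(-0.5 + log(3) * (rec$strong == "yes") +
                log(1.5) * (rec$weak == "yes"))
  rec$disease <- factor(ifelse(rbinom(n, 1, p) == 1, "with_disease",
                               "without_disease"),
                        levels = c("without_disease", "with_disease"))
  eff <- estimate_odds_ratios(rec, "disease", c("strong", "weak"))
  m <- assemble_model(eff, rec)
  # hierarchical order: larger standardized contribution first
  expect_equal(names(m$factors)[1], "strong")
  # weights are exactly OR - 1
  or_strong <- eff$odds_ratio[eff$variable == "strong"]
  expect_equal(unname(m$factors$strong$weights["yes"]), or_strong - 1)
  # VIFs near 1 for independent factors
  expect_true(all(eff$vif < 1.1))
  # round-trip: scoring reproduces a direct threshold computation
  scores <- score_records(rec, m)
  w <- c(strong = unname(m$factors$strong$weights["yes"]),
         weak = unname(m$factors$weak$weights["yes"]))
  direct <- w["strong"] * (rec$strong == "yes") +
    w["weak"] * (rec$weak == "yes")
  expect_equal(scores, unname(direct))
  cut <- m$cutoffs[["mod_min"]]
  expect_equal(mean(dichotomize(classify_risk(scores, m)) == "positive"),
               mean(direct >= cut))
})

test_that("single-factor model scores any at-risk subject at OR - 1", {
  rec <- tiny_cohort(4000, or = 4.0, seed = 8)
  eff <- estimate_odds_ratios(rec, "disease", "exposure")
  m <- assemble_model(eff, rec)
  s <- risk_score(c(exposure = "yes"), m)
  expect_equal(s, eff$odds_ratio - 1)
  expect_equal(risk_score(c(exposure = "no"), m), 0)
})
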
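#' Specify a synthetic screening population
#'
#' Describes the generative model for a synthetic adolescent screening
#' cohort: per-factor marginal level probabilities, true log-odds
#' coefficients per non-referent level, a target marginal disease
#' prevalence that the intercept is calibrated to hit, a severity model for
#' DMFT given disease, and the stratification into academic years.
#'
#' @param factors list of factor specifications, each a list with `name`,
#'   `levels`, `probs` (named marginal probabilities summing to 1),
#'   `referent`, and `log_or` (named true log odds ratios for non-referent
#'   levels; omitted levels have log odds ratio 0).
#' @param target_prevalence marginal disease probability the intercept is
#'   calibrated against; default 0.66.
#' @param severity_mean mean DMFT among the diseased; the conditional DMFT
#'   is `1 + Poisson(severity_mean - 1)` (capped at 32), so the default 3.2
#'   places the diseased-group mean in the WHO Moderate band.
#' @param n_strata number of strata ("academic years"); default 6.
#' @param n_per_stratum records per stratum; default 8550 (six strata give
#'   a cohort of 51,300).
#' @param seed root random seed; per-stratum substreams are derived from it
#'   deterministically.
#' @param intercept optional fixed log-odds intercept; when supplied,
#'   generation uses it directly and skips prevalence calibration.
#' @return an object of class `population_config`.
#' @export
population_config <- function(factors, target_prevalence = 0.66,
                              severity_mean = 3.2, n_strata = 6,
                              n_per_stratum = 8550, seed = 20021,
                              intercept = NULL) {
  if (!length(factors)) stop("at least one factor is required", call. = FALSE)
  for (f in factors) {
    if (!all(c("name", "levels", "probs", "referent") %in% names(f))) {
      stop("each factor needs name, levels, probs, referent", call. = FALSE)
    }
    if (!setequal(names(f$probs), f$levels)) {
      stop("factor '", f$name, "': probs must be named by its levels",
           call. = FALSE)
    }
    if (any(f$probs < 0) || abs(sum(f$probs) - 1) > 1e-8) {
      stop("factor '", f$name, "': level probabilities must be ",
           "non-negative and sum to 1", call. = FALSE)
    }
    if (!f$referent %in% f$levels) {
      stop("factor '", f$name, "': referent not among levels", call. = FALSE)
    }
    bad <- setdiff(names(f$log_or), setdiff(f$levels, f$referent))
    if (length(bad)) {
      stop("factor '", f$name, "': log_or names must be non-referent ",
           "levels (offending: ", paste(bad, collapse = ", "), ")",
           call. = FALSE)
    }
  }
  if (target_prevalence <= 0 || target_prevalence >= 1) {
    stop("'target_prevalence' must be in (0, 1)", call. = FALSE)
  }
  if (severity_mean < 1) {
    stop("'severity_mean' must be >= 1 (diseased have DMFT >= 1)",
         call. = FALSE)
  }
  if (n_strata < 1 || n_per_stratum < 0) {
    stop("'n_strata' must be >= 1 and 'n_per_stratum' >= 0", call. = FALSE)
  }
  structure(
    list(factors = factors, target_prevalence = target_prevalence,
         severity_mean = severity_mean, n_strata = as.integer(n_strata),
         n_per_stratum = as.integer(n_per_stratum),
         seed = as.integer(seed), intercept = intercept),
    class = "population_config"
  )
}

#' Default ten-factor synthetic population
#'
#' Mirrors the structure of the screening instrument's ten demographic
#' factors (fluoridation exposure, environmental smoke, race, age, locale,
#' tobacco use, BMI, insurance status, sex, sealants) with illustrative
#' marginals and true odds ratios equal to those of the packaged default
#' model configuration, a 0.66 target prevalence, and six strata of 8,550
#' records (a 51,300-record cohort).
#'
#' @param ... overrides passed on to [population_config()].
#' @return a [population_config()].
#' @export
default_population_config <- function(...) {
  f <- function(name, probs, referent, or) {
    list(name = name, levels = names(probs), probs = probs,
         referent = referent, log_or = log(or))
  }
  factors <- list(
    f("fluoridation", c(fluoridated = 0.6, nonfluoridated = 0.4),
      "fluoridated", c(nonfluoridated = 2.1)),
    f("smoke_exposure", c(not_exposed = 0.7, exposed = 0.3),
      "not_exposed", c(exposed = 1.9)),
    f("race", c(white = 0.45, black = 0.1, hispanic = 0.3, other = 0.15),
      "white", c(black = 1.8, hispanic = 1.6, other = 1.3)),
    f("age", c("13-14" = 0.35, "15-16" = 0.35, "17-18" = 0.3),
      "13-14", c("15-16" = 1.3, "17-18" = 1.5)),
    f("locale", c(metro = 0.85, rural = 0.15), "metro", c(rural = 1.5)),
    f("tobacco_use", c(nonuser = 0.85, user = 0.15), "nonuser",
      c(user = 1.6)),
    f("bmi", c(normal = 0.7, overweight = 0.3), "normal",
      c(overweight = 1.4)),
    f("insurance", c(insured = 0.75, uninsured = 0.25), "insured",
      c(uninsured = 1.4)),
    f("sex", c(female = 0.5, male = 0.5), "female", c(male = 1.2)),
    f("sealants", c(present = 0.4, absent = 0.6), "present",
      c(absent = 1.5))
  )
  population_config(factors = factors, ...)
}

factor_effect <- function(f) {
  eta <- stats::setNames(rep(0, length(f$levels)), f$levels)
  if (length(f$log_or)) eta[names(f$log_or)] <- f$log_or
  eta
}

#' Calibrate the logistic intercept to the target prevalence
#'
#' Finds the intercept at which the population-averaged disease probability
#' — the exact expectation of the logistic probability over all factor-level
#' combinations under the independent marginals — equals the configured
#' target prevalence.  The averaged probability is strictly increasing in
#' the intercept, so a bracketed root search converges unconditionally.
#'
#' @param config a [population_config()].
#' @param tol absolute tolerance on the achieved prevalence; default 1e-6.
#' @return the calibrated intercept (log-odds scale).
#' @export
calibrate_intercept <- function(config, tol = 1e-6) {
  stopifnot(inherits(config, "population_config"))
  effects <- lapply(config$factors, factor_effect)
  probs <- lapply(config$factors, function(f) f$probs[f$levels])
  n_combo <- prod(vapply(effects, length, numeric(1)))
  if (n_combo > 1e6) {
    stop("factor-level combinations exceed 1e6; enumeration not feasible",
         call. = FALSE)
  }
  # joint distribution of the linear predictor offset under independence
  eta <- 0
  w <- 1
  for (i in seq_along(effects)) {
    eta <- as.vector(outer(eta, effects[[i]], `+`))
    w <- as.vector(outer(w, unname(probs[[i]]), `*`))
  }
  if (!any(w > 0)) stop("degenerate factor distribution", call. = FALSE)
  target <- config$target_prevalence
  avg_prev <- function(b0) sum(w * stats::plogis(b0 + eta)) - target
  lo <- -35; hi <- 35
  if (avg_prev(lo) > 0 || avg_prev(hi) < 0) {
    stop("target prevalence unreachable for this configuration",
         call. = FALSE)
  }
  r <- stats::uniroot(avg_prev, c(lo, hi), tol = tol / 10)
  b0 <- r$root
  if (abs(avg_prev(b0)) > tol) {
    stop("intercept calibration did not reach the target prevalence within ",
         tol, call. = FALSE)
  }
  b0
}

stratum_seeds <- function(config) {
  set.seed(config$seed)
  sample.int(2147483646L, config$n_strata)
}

#' Generate a synthetic screening cohort
#'
#' Draws factor levels independently from the configured marginals, disease
#' status from the logistic model with the calibrated (or fixed) intercept,
#' and DMFT: 0 for the disease-free, `1 + Poisson(severity_mean - 1)`
#' (capped at 32) for the diseased, split into decayed/missing/filled
#' components.  Every stratum uses its own deterministic substream of the
#' root seed, so strata are independently reproducible and the whole cohort
#' is identical across runs with the same seed.
#'
#' @param config a [population_config()].
#' @return data frame with columns `record_id`, `year`, one column per
#'   factor (as a factor, referent level first), `disease_prob`, `disease`
#'   (a [disease_status()] factor), `dmft_d`, `dmft_m`, `dmft_f`.  The
#'   intercept used is attached as attribute `"intercept"`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  b0 <- if (!is.null(config$intercept)) config$intercept
        else calibrate_intercept(config)
  seeds <- stratum_seeds(config)
  n <- config$n_per_stratum
  strata <- lapply(seq_len(config$n_strata), function(s) {
    set.seed(seeds[s])
    if (n == 0) return(NULL)
    eta <- rep(b0, n)
    cols <- list()
    for (f in config$factors) {
      lev <- sample(f$levels, n, replace = TRUE, prob = f$probs[f$levels])
      eff <- factor_effect(f)
      eta <- eta + eff[lev]
      cols[[f$name]] <- factor(lev, levels = c(
        f$referent, setdiff(f$levels, f$referent)))
    }
    p <- stats::plogis(eta)
    dis <- stats::rbinom(n, 1, p)
    total <- ifelse(dis == 1,
                    pmin(1 + stats::rpois(n, config$severity_mean - 1), 32),
                    0)
    comp <- t(vapply(total, function(tt) {
      if (tt == 0) c(0L, 0L, 0L)
      else as.integer(stats::rmultinom(1, tt, prob = c(0.6, 0.1, 0.3)))
    }, integer(3)))
    out <- data.frame(year = paste0("year_", s), cols,
                      disease_prob = unname(p),
                      disease = factor(
                        ifelse(dis == 1, "with_disease", "without_disease"),
                        levels = c("without_disease", "with_disease")),
                      dmft_d = comp[, 1], dmft_m = comp[, 2],
                      dmft_f = comp[, 3],
                      check.names = FALSE)
    out
  })
  cohort <- do.call(rbind, strata)
  if (is.null(cohort)) {
    cohort <- data.frame(year = character())
  }
  if (nrow(cohort)) {
    cohort <- cbind(record_id = sprintf("r%07d", seq_len(nrow(cohort))),
                    cohort)
  }
  attr(cohort, "intercept") <- b0
  attr(cohort, "config") <- config
  cohort
}

#' End-to-end parameter-recovery experiment
#'
#' Generates a cohort with known coefficients, refits the odds ratios by
#' logistic regression, assembles a risk model from the estimates, scores
#' the cohort, and validates the resulting screening test against the DMFT
#' gold standard per stratum — a closed loop exercising every stage of the
#' pipeline against known truth.
#'
#' @param config a [population_config()].
#' @param cutoffs [risk_cutoffs()] used for the assembled instrument.
#' @param level,ci_method passed to [summarize_years()].
#' @return list with `cohort` size `n`, `intercept` (true, calibrated),
#'   `effects` (the fitted effects), `or_recovery` (data frame of true vs
#'   estimated odds ratios per non-referent level), `model` (the assembled
#'   [risk_model()]), `tables` (per-stratum [two_by_two()]), and `validity`
#'   (a [summarize_years()] summary, or `NULL` with a `degenerate` note
#'   when the screening result is one-sided and the predictive values are
#'   undefined).
#' @export
recovery_experiment <- function(config, cutoffs = risk_cutoffs(),
                                level = 0.95, ci_method = "wilson") {
  stopifnot(inherits(config, "population_config"))
  cohort <- generate_population(config)
  if (!nrow(cohort)) stop("empty cohort", call. = FALSE)
  vars <- vapply(config$factors, `[[`, character(1), "name")
  eff <- estimate_odds_ratios(cohort, "disease", vars)
  truth <- do.call(rbind, lapply(config$factors, function(f) {
    lv <- setdiff(f$levels, f$referent)
    eta <- factor_effect(f)
    data.frame(variable = f$name, level = lv,
               true_or = exp(unname(eta[lv])), row.names = NULL)
  }))
  rec <- merge(truth, eff[, c("variable", "level", "odds_ratio")],
               by = c("variable", "level"), sort = FALSE)
  names(rec)[names(rec) == "odds_ratio"] <- "estimated_or"
  rec$rel_error <- rec$estimated_or / rec$true_or - 1
  model <- assemble_model(eff, cohort, cutoffs)
  scores <- score_records(cohort, model)
  result <- dichotomize(classify_risk(scores, model))
  status <- disease_status(dmft_from_records(cohort))
  tables <- lapply(split(seq_len(nrow(cohort)), cohort$year), function(i) {
    build_table(result[i], status[i], label = cohort$year[i[1]])
  })
  validity <- tryCatch(
    summarize_years(tables, level = level, ci_method = ci_method),
    error = function(e) NULL)
  degenerate <- if (is.null(validity)) {
    paste("screening result is one-sided (positivity rate",
          signif(mean(result == "positive"), 3),
          "); predictive values undefined")
  } else NULL
  list(n = nrow(cohort), intercept = attr(cohort, "intercept"),
       effects = eff, or_recovery = rec, model = model,
       scores = scores, tables = tables, validity = validity,
       degenerate = degenerate)
}
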
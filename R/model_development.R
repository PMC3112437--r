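#' Screen candidate variables against caries severity
#'
#' First stage of instrument construction: an ordinary least-squares fit of
#' the DMFT total (the severity measure) on all candidate factors at once,
#' retaining each variable whose contribution is significant at `alpha`.
#' Significance per variable is the single-deletion F test, which handles
#' multi-level factors as a unit.
#'
#' @param records data frame holding the candidate factor columns.
#' @param outcome numeric vector of DMFT totals (length `nrow(records)`),
#'   or the name of a column of `records`.
#' @param variables character vector of candidate factor column names.
#' @param alpha retention significance level; default 0.05.
#' @return data frame of class `variable_screen` with columns `variable`,
#'   `df`, `f_value`, `p_value`, `retained`.
#' @export
screen_variables <- function(records, outcome, variables, alpha = 0.05) {
  stopifnot(is.data.frame(records))
  if (is.character(outcome) && length(outcome) == 1L) {
    outcome <- records[[outcome]]
  }
  outcome <- as.numeric(outcome)
  if (length(outcome) != nrow(records)) {
    stop("'outcome' must have one value per record", call. = FALSE)
  }
  if (length(unique(outcome)) < 2) {
    stop("outcome is constant; nothing to screen against", call. = FALSE)
  }
  miss <- setdiff(variables, names(records))
  if (length(miss)) {
    stop("records are missing variable(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) {
    stop("'alpha' must be in [0, 1]", call. = FALSE)
  }
  dat <- records[, variables, drop = FALSE]
  dat[] <- lapply(dat, function(x) if (is.numeric(x)) x else factor(x))
  dat$.outcome <- outcome
  fit <- stats::lm(.outcome ~ ., data = dat)
  if (nrow(dat) <= length(stats::coef(fit))) {
    stop("fewer observations than design columns", call. = FALSE)
  }
  al <- stats::alias(fit)$Complete
  if (!is.null(al)) {
    stop("rank-deficient design; aliased columns: ",
         paste(rownames(al), collapse = ", "), call. = FALSE)
  }
  dr <- stats::drop1(fit, test = "F")
  dr <- dr[variables, , drop = FALSE]
  res <- data.frame(variable = variables,
                    df = dr$Df,
                    f_value = dr$`F value`,
                    p_value = dr$`Pr(>F)`,
                    row.names = NULL)
  res$retained <- res$p_value < alpha
  class(res) <- c("variable_screen", "data.frame")
  res
}

# per-design-column variance inflation factor: diag of the inverse
# correlation matrix of the (intercept-free) design
design_vif <- function(X) {
  keep <- apply(X, 2, stats::sd) > 0
  v <- rep(NA_real_, ncol(X))
  names(v) <- colnames(X)
  if (sum(keep) >= 2) {
    v[keep] <- diag(solve(stats::cor(X[, keep, drop = FALSE])))
  } else if (sum(keep) == 1) {
    v[keep] <- 1
  }
  v
}

#' Estimate per-factor odds ratios by logistic regression
#'
#' Second stage of instrument construction: a maximum-likelihood logistic
#' fit of dichotomous disease status on the retained factors with indicator
#' (dummy) coding against each factor's referent level.  Odds ratios are
#' `exp(coefficient)`; standardized beta weights (coefficient times design-
#' column standard deviation) order the factors by relative contribution,
#' and per-column variance inflation factors flag multicollinearity.
#'
#' @param records data frame holding the factor columns.
#' @param status disease status: a factor from [disease_status()], a
#'   logical/0-1 vector, or the name of a column of `records`.
#' @param variables character vector of factor column names.  Character
#'   columns are coded against their first sorted level unless already
#'   factors (set the referent by releveling).
#' @param epsilon convergence tolerance on the relative deviance change
#'   (default 1e-8).
#' @param vif_threshold variance inflation factor above which a warning is
#'   issued (default 10).
#' @return object of class `fitted_effects`: a data frame with one row per
#'   non-referent design column (`variable`, `level`, `estimate`, `se`,
#'   `odds_ratio`, `std_beta`, `vif`), with the fitted `glm` attached as
#'   attribute `"fit"`.
#' @export
estimate_odds_ratios <- function(records, status, variables,
                                 epsilon = 1e-8, vif_threshold = 10) {
  stopifnot(is.data.frame(records))
  if (is.character(status) && length(status) == 1L &&
      status %in% names(records)) {
    status <- records[[status]]
  }
  y <- if (is.factor(status)) as.integer(status == "with_disease")
       else as.integer(as.logical(status))
  if (length(y) != nrow(records) || anyNA(y)) {
    stop("'status' must be a complete disease-status vector, one per record",
         call. = FALSE)
  }
  if (length(unique(y)) < 2) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  miss <- setdiff(variables, names(records))
  if (length(miss)) {
    stop("records are missing variable(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dat <- records[, variables, drop = FALSE]
  dat[] <- lapply(dat, function(x) if (is.numeric(x)) x else factor(x))
  dat$.y <- y
  fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial(),
                    control = stats::glm.control(epsilon = epsilon,
                                                 maxit = 100))
  if (!fit$converged) {
    stop("logistic fit did not converge", call. = FALSE)
  }
  cf <- summary(fit)$coefficients
  if (anyNA(stats::coef(fit))) {
    stop("rank-deficient design; aliased terms: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  }
  mu <- fit$fitted.values
  if (max(abs(stats::coef(fit))) > 15 ||
      min(mu) < 1e-10 || max(mu) > 1 - 1e-10) {
    stop("(quasi-)complete separation detected: fitted probabilities ",
         "numerically 0 or 1 / diverging coefficients", call. = FALSE)
  }
  X <- stats::model.matrix(fit)[, -1, drop = FALSE]
  keep <- rownames(cf) != "(Intercept)"
  sds <- apply(X, 2, stats::sd)[rownames(cf)[keep]]
  vifs <- design_vif(X)[rownames(cf)[keep]]
  # map each design column back to its source variable
  assign_idx <- attr(stats::model.matrix(fit), "assign")[-1]
  term_vars <- attr(fit$terms, "term.labels")[assign_idx]
  res <- data.frame(
    term = rownames(cf)[keep],
    variable = term_vars,
    level = gsub("`", "", mapply(function(trm, v)
      sub(v, "", trm, fixed = TRUE), rownames(cf)[keep], term_vars),
      fixed = TRUE),
    estimate = cf[keep, "Estimate"],
    se = cf[keep, "Std. Error"],
    odds_ratio = exp(cf[keep, "Estimate"]),
    std_beta = cf[keep, "Estimate"] * sds,
    vif = vifs,
    row.names = NULL
  )
  high <- res$variable[!is.na(res$vif) & res$vif > vif_threshold]
  if (length(high)) {
    warning("variance inflation above ", vif_threshold, " for: ",
            paste(unique(high), collapse = ", "), call. = FALSE)
  }
  res$level[res$level == ""] <- NA_character_
  attr(res, "fit") <- fit
  attr(res, "intercept") <- unname(stats::coef(fit)[1])
  class(res) <- c("fitted_effects", "data.frame")
  res
}

#' Assemble a risk model from fitted effects
#'
#' Converts fitted odds ratios into additive instrument weights (odds ratio
#' minus one, referent zero), orders the factors by descending standardized
#' contribution (a multi-level factor is ranked by its largest absolute
#' standardized beta), and attaches the category cut-offs.  Any fitted
#' protective level is re-referenced inside [risk_factor()] so all stored
#' weights are non-negative.
#'
#' @param effects a `fitted_effects` object from [estimate_odds_ratios()].
#' @param records the data frame the effects were fitted on (supplies the
#'   full level sets and referent levels).
#' @param cutoffs a [risk_cutoffs()] object; required.
#' @return a [risk_model()].
#' @export
assemble_model <- function(effects, records, cutoffs = risk_cutoffs()) {
  stopifnot(inherits(effects, "fitted_effects"), is.data.frame(records))
  if (is.null(cutoffs)) stop("cut-offs must be supplied", call. = FALSE)
  if (!inherits(cutoffs, "risk_cutoffs")) {
    cutoffs <- do.call(risk_cutoffs, as.list(cutoffs))
  }
  vars <- unique(effects$variable)
  rank_stat <- vapply(vars, function(v)
    max(abs(effects$std_beta[effects$variable == v])), numeric(1))
  vars <- vars[order(-rank_stat)]
  factors <- lapply(vars, function(v) {
    col <- factor(records[[v]])
    rows <- effects[effects$variable == v, , drop = FALSE]
    ors <- stats::setNames(rows$odds_ratio, rows$level)
    risk_factor(v, levels = levels(col), referent = levels(col)[1],
                odds_ratios = ors)
  })
  risk_model(factors, cutoffs)
}
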
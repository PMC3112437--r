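#' Two-by-two screening classification table
#'
#' Cross-classifies a screening result (positive/negative) against the gold
#' standard (with/without disease) for one stratum, e.g. one academic year.
#' Marginals are always recomputed from the four cells, never trusted from
#' input; use [validate_table_consistency()] to audit externally printed
#' marginals.
#'
#' @param tp true positives: test-positive, with disease.
#' @param fp false positives: test-positive, without disease.
#' @param fn false negatives: test-negative, with disease.
#' @param tn true negatives: test-negative, without disease.
#' @param label optional stratum identifier.
#' @return an object of class `two_by_two`.
#' @export
two_by_two <- function(tp, fp, fn, tn, label = NULL) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  structure(list(tp = as.numeric(tp), fp = as.numeric(fp),
                 fn = as.numeric(fn), tn = as.numeric(tn),
                 label = label),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  cat("2x2 screening table",
      if (!is.null(x$label)) paste0("[", x$label, "]"), "\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("test positive", "test negative"),
                              c("with disease", "without disease")))
  print(addmargins(as.table(m)))
  invisible(x)
}

table_total <- function(t) t$tp + t$fp + t$fn + t$tn

#' Build a two-by-two table from paired classifications
#'
#' Pairwise matching of each subject's screening result with their
#' gold-standard disease status; every pair lands in exactly one cell, so
#' the cells sum to the number of pairs.
#'
#' @param result vector of screening results (`"positive"`/`"negative"`),
#'   e.g. from [dichotomize()].
#' @param status vector of disease statuses
#'   (`"with_disease"`/`"without_disease"`), e.g. from [disease_status()].
#' @param label optional stratum identifier.
#' @return a [two_by_two()] table.
#' @export
build_table <- function(result, status, label = NULL) {
  result <- as.character(result)
  status <- as.character(status)
  if (length(result) == 0L) stop("no classification pairs supplied", call. = FALSE)
  if (length(result) != length(status)) {
    stop("'result' and 'status' must have equal length", call. = FALSE)
  }
  if (!all(result %in% c("positive", "negative"))) {
    stop("screening results must be 'positive' or 'negative'", call. = FALSE)
  }
  if (!all(status %in% c("with_disease", "without_disease"))) {
    stop("disease status must be 'with_disease' or 'without_disease'",
         call. = FALSE)
  }
  pos <- result == "positive"
  dis <- status == "with_disease"
  two_by_two(tp = sum(pos & dis), fp = sum(pos & !dis),
             fn = sum(!pos & dis), tn = sum(!pos & !dis), label = label)
}

metric_guard <- function(denom, what, t) {
  if (denom <= 0) {
    stop(what, " is undefined",
         if (!is.null(t$label)) paste0(" for stratum '", t$label, "'"),
         ": empty denominator", call. = FALSE)
  }
}

#' Sensitivity, specificity, predictive values and prevalence
#'
#' Standard epidemiologic definitions on a [two_by_two()] table:
#' sensitivity TP/(TP+FN), specificity TN/(TN+FP), predictive value
#' positive TP/(TP+FP), predictive value negative TN/(TN+FN), prevalence
#' (TP+FN)/total.  Each errors rather than returning NaN when its
#' denominator is empty.
#'
#' @param t a [two_by_two()] table.
#' @return a proportion in \[0, 1\].
#' @examples
#' t <- two_by_two(tp = 4098, fp = 407, fn = 1366, tn = 2304)
#' sensitivity(t)   # 0.75
#' specificity(t)   # 0.8499...
#' @export
sensitivity <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  metric_guard(t$tp + t$fn, "sensitivity", t)
  t$tp / (t$tp + t$fn)
}

#' @rdname sensitivity
#' @export
specificity <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  metric_guard(t$tn + t$fp, "specificity", t)
  t$tn / (t$tn + t$fp)
}

#' @rdname sensitivity
#' @export
pvp <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  metric_guard(t$tp + t$fp, "predictive value positive", t)
  t$tp / (t$tp + t$fp)
}

#' @rdname sensitivity
#' @export
pvn <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  metric_guard(t$tn + t$fn, "predictive value negative", t)
  t$tn / (t$tn + t$fn)
}

#' @rdname sensitivity
#' @export
prevalence <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  metric_guard(table_total(t), "prevalence", t)
  (t$tp + t$fn) / table_total(t)
}

#' Confidence interval for a binomial proportion
#'
#' Wilson score interval (default) or Wald.  The Wilson interval always
#' lies within \[0, 1\] and contains the point estimate; the Wald interval
#' is provided for comparison and is truncated to \[0, 1\].
#'
#' @param p_hat observed proportion in \[0, 1\].
#' @param n number of trials (>= 1).
#' @param level confidence level in (0, 1); default 0.95.
#' @param method `"wilson"` or `"wald"`.
#' @return named numeric vector `c(lower, upper)`.
#' @export
proportion_ci <- function(p_hat, n, level = 0.95,
                          method = c("wilson", "wald")) {
  method <- match.arg(method)
  if (!is.finite(p_hat) || p_hat < 0 || p_hat > 1) {
    stop("'p_hat' must be a proportion in [0, 1]", call. = FALSE)
  }
  if (!is.finite(n) || n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (!is.finite(level) || level <= 0 || level >= 1) {
    stop("'level' must be in (0, 1)", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "wilson") {
    centre <- (p_hat + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    out <- c(lower = max(0, centre - half), upper = min(1, centre + half))
    # analytically the bounds hit 0/1 exactly at degenerate p_hat; guard
    # the floating-point residue so the interval always contains p_hat
    if (p_hat == 0) out["lower"] <- 0
    if (p_hat == 1) out["upper"] <- 1
  } else {
    half <- z * sqrt(p_hat * (1 - p_hat) / n)
    out <- c(lower = max(0, p_hat - half), upper = min(1, p_hat + half))
  }
  out
}

#' All five validity metrics for one stratum, with confidence intervals
#'
#' @param t a [two_by_two()] table.
#' @param level confidence level for the intervals.
#' @param ci_method `"wilson"` (default) or `"wald"`.
#' @return data frame with one row per metric: `metric`, `estimate`,
#'   `lower`, `upper`, `n` (the metric's denominator), `level`.
#' @export
screening_metrics <- function(t, level = 0.95, ci_method = "wilson") {
  stopifnot(inherits(t, "two_by_two"))
  est <- c(sensitivity = sensitivity(t), specificity = specificity(t),
           pvp = pvp(t), pvn = pvn(t), prevalence = prevalence(t))
  n <- c(t$tp + t$fn, t$tn + t$fp, t$tp + t$fp, t$tn + t$fn, table_total(t))
  ci <- t(mapply(proportion_ci, est, n,
                 MoreArgs = list(level = level, method = ci_method)))
  data.frame(stratum = if (is.null(t$label)) NA_character_ else t$label,
             metric = names(est), estimate = unname(est),
             lower = ci[, "lower"], upper = ci[, "upper"],
             n = n, level = level, row.names = NULL)
}

#' Round half away from zero
#'
#' Display rounding for the instrument's integer-percent reporting (a value
#' of x.5 rounds up, unlike [round()]'s round-half-even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Summarize screening validity across strata
#'
#' Computes the five metrics per stratum, then the unweighted arithmetic
#' mean of each metric across strata (not pooled-cell metrics), alongside
#' integer-percent display values rounded half-up.
#'
#' @param tables list of [two_by_two()] tables, one per stratum.
#' @param level,ci_method passed to [screening_metrics()].
#' @return object of class `multiyear_summary`: list with `per_stratum`
#'   (data frame, full precision plus `percent` column), `means` (named
#'   numeric, full precision), `mean_percent` (rounded), `n_total`.
#' @export
summarize_years <- function(tables, level = 0.95, ci_method = "wilson") {
  if (inherits(tables, "two_by_two")) tables <- list(tables)
  if (!length(tables) || !all(vapply(tables, inherits, logical(1),
                                     "two_by_two"))) {
    stop("'tables' must be a non-empty list of two_by_two tables",
         call. = FALSE)
  }
  per <- do.call(rbind, lapply(seq_along(tables), function(i) {
    t <- tables[[i]]
    m <- screening_metrics(t, level = level, ci_method = ci_method)
    if (is.na(m$stratum[1])) m$stratum <- paste0("stratum_", i)
    m
  }))
  per$percent <- round_half_up(100 * per$estimate)
  means <- tapply(per$estimate, per$metric, mean)
  means <- means[c("sensitivity", "specificity", "pvp", "pvn", "prevalence")]
  means <- stats::setNames(as.numeric(means), names(means))
  structure(
    list(per_stratum = per,
         means = means,
         mean_percent = round_half_up(100 * means),
         n_total = sum(vapply(tables, table_total, numeric(1))),
         level = level, ci_method = ci_method),
    class = "multiyear_summary"
  )
}

#' @export
print.multiyear_summary <- function(x, ...) {
  wide <- stats::reshape(
    x$per_stratum[, c("stratum", "metric", "percent")],
    idvar = "stratum", timevar = "metric", direction = "wide")
  names(wide) <- sub("^percent\\.", "", names(wide))
  wide <- wide[, c("stratum", "sensitivity", "specificity", "pvp", "pvn",
                   "prevalence")]
  avg <- data.frame(stratum = "mean", t(x$mean_percent))
  names(avg) <- names(wide)
  cat("Screening validity by stratum (integer %, ",
      x$ci_method, " CIs at level ", x$level, "):\n", sep = "")
  print(rbind(wide, avg), row.names = FALSE)
  cat("Total screened:", x$n_total, "\n")
  invisible(x)
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' Standard formula `k/(k-1) * (1 - sum of item variances / variance of the
#' item total)` on an observations-by-items matrix.
#'
#' @param m numeric matrix or data frame, rows = observations, columns =
#'   items (>= 2 of each).
#' @return alpha, a real number <= 1.
#' @export
cronbach_alpha <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2 || nrow(m) < 2) {
    stop("alpha needs at least 2 items and 2 observations", call. = FALSE)
  }
  total_var <- stats::var(rowSums(m))
  if (!is.finite(total_var) || total_var == 0) {
    stop("alpha is undefined: zero or degenerate total variance",
         call. = FALSE)
  }
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' Audit printed marginals against cell sums
#'
#' Published tables sometimes print row/column totals that do not equal the
#' sums of their cells.  This check compares any supplied printed marginals
#' with the marginals recomputed from the four cells and reports every
#' mismatch; an empty result means full agreement.
#'
#' @param t a [two_by_two()] table.
#' @param printed named list or vector with any of `test_positive_total`
#'   (tp+fp), `test_negative_total` (fn+tn), `diseased_total` (tp+fn),
#'   `nondiseased_total` (fp+tn), `grand_total`.
#' @return character vector of discrepancy descriptions (empty if none).
#' @export
validate_table_consistency <- function(t, printed) {
  stopifnot(inherits(t, "two_by_two"))
  printed <- as.list(printed)
  expected <- list(test_positive_total = t$tp + t$fp,
                   test_negative_total = t$fn + t$tn,
                   diseased_total = t$tp + t$fn,
                   nondiseased_total = t$fp + t$tn,
                   grand_total = table_total(t))
  out <- character()
  for (nm in intersect(names(printed), names(expected))) {
    p <- as.numeric(printed[[nm]])
    if (!is.na(p) && p != expected[[nm]]) {
      out <- c(out, sprintf("%s%s: printed %s but cells sum to %s",
                            if (!is.null(t$label)) paste0(t$label, " ") else "",
                            nm, format(p), format(expected[[nm]])))
    }
  }
  out
}

#' The six Nevada academic-year two-by-two tables
#'
#' Loads the packaged transcription of the published per-year screening
#' classification counts (academic years 2002/2003 through 2007/2008) as a
#' list of [two_by_two()] tables.  The fixture also records the totals as
#' printed, which for one year disagree with the cell sums — see
#' [validate_table_consistency()].
#'
#' @param path optional override of the packaged fixture file.
#' @return named list of six [two_by_two()] tables; the raw fixture rows
#'   (including printed marginals) are attached as attribute `"fixture"`.
#' @export
nevada_tables <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table2_nevada.csv", package = "cariesrisk")
  }
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  tabs <- lapply(seq_len(nrow(raw)), function(i) {
    with(raw[i, ], two_by_two(tp, fp, fn, tn, label = year))
  })
  names(tabs) <- raw$year
  attr(tabs, "fixture") <- raw
  tabs
}
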
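#' Convert odds ratios to additive risk weights
#'
#' The screening instrument assigns each at-risk factor level a weight equal
#' to its odds ratio minus one, so that the referent level (odds ratio 1,
#' equal risk) carries weight zero and the instrument's "no risk" column is
#' zeroed out.  Weights from all factors are then summed into a total risk
#' score.
#'
#' @param odds_ratios named numeric vector of odds ratios, one per
#'   non-referent level.  All must be strictly positive.
#' @return named numeric vector of weights (`odds_ratios - 1`).
#' @examples
#' weights_from_odds_ratios(c(exposed = 2.4))        # 1.4
#' weights_from_odds_ratios(c(a = 1.5, b = 3.0))     # 0.5, 2.0
#' @export
weights_from_odds_ratios <- function(odds_ratios) {
  if (!is.numeric(odds_ratios) || length(odds_ratios) == 0) {
    stop("'odds_ratios' must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(odds_ratios)) || any(odds_ratios <= 0)) {
    stop("all odds ratios must be finite and > 0", call. = FALSE)
  }
  odds_ratios - 1
}

#' Define a risk factor for the screening instrument
#'
#' A risk factor has a set of category levels, a referent level with weight
#' zero, and a non-negative additive weight (odds ratio minus one) for every
#' other level.  The instrument's score column only ever *adds* risk, so a
#' protective level (odds ratio below 1 relative to the supplied referent)
#' is handled by re-choosing the referent: all odds ratios are rescaled
#' relative to the least-risky level, which becomes the new referent.  For a
#' binary factor with protective odds ratio r this gives the familiar
#' `1/r - 1` weight on the at-risk level.
#'
#' @param name factor identifier, e.g. `"sealants"`.
#' @param levels character vector of category labels.
#' @param referent the zero-weight level; must be one of `levels`.
#' @param odds_ratios named numeric vector of odds ratios for the
#'   non-referent levels (relative to `referent`).  Levels omitted from
#'   `odds_ratios` are treated as odds ratio 1.
#' @return an object of class `risk_factor`.
#' @export
risk_factor <- function(name, levels, referent, odds_ratios = numeric()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  levels <- as.character(levels)
  if (anyDuplicated(levels)) {
    stop("factor '", name, "': duplicate levels", call. = FALSE)
  }
  if (!referent %in% levels) {
    stop("factor '", name, "': referent '", referent,
         "' is not one of the levels", call. = FALSE)
  }
  extra <- setdiff(names(odds_ratios), levels)
  if (length(extra)) {
    stop("factor '", name, "': odds ratios supplied for unknown levels: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (referent %in% names(odds_ratios) && odds_ratios[[referent]] != 1) {
    stop("factor '", name, "': the referent level must have odds ratio 1",
         call. = FALSE)
  }
  ors <- stats::setNames(rep(1, length(levels)), levels)
  if (length(odds_ratios)) {
    if (any(!is.finite(odds_ratios)) || any(odds_ratios <= 0)) {
      stop("factor '", name, "': all odds ratios must be finite and > 0",
           call. = FALSE)
    }
    ors[names(odds_ratios)] <- odds_ratios
  }
  # re-reference so every stored weight is >= 0
  if (min(ors) < 1) {
    new_ref <- levels[which.min(ors)]
    ors <- ors / min(ors)
    referent <- new_ref
  }
  weights <- weights_from_odds_ratios(ors)
  weights[referent] <- 0
  structure(
    list(name = name, levels = levels, referent = referent,
         weights = weights),
    class = "risk_factor"
  )
}

#' @export
print.risk_factor <- function(x, ...) {
  cat("Risk factor:", x$name, "\n")
  w <- ifelse(names(x$weights) == x$referent, "0 (referent)",
              formatC(x$weights, format = "fg"))
  cat(paste0("  ", format(names(x$weights)), "  ", w, collapse = "\n"), "\n")
  invisible(x)
}

#' Risk-score category cut-offs
#'
#' The instrument repurposes the WHO mean-DMFT population benchmarks as
#' score cut-offs: Low <= 2.6, Moderate 2.7-4.4, High >= 4.5.  The printed
#' categories leave the open interval (2.6, 2.7) unassigned; because scores
#' are continuous the boundaries are implemented as half-open intervals
#' Low = [0, mod_min), Moderate = [mod_min, high_min), High = [high_min,
#' Inf), which reproduces the printed label at every printed boundary value.
#'
#' @param low_max upper printed boundary of the Low band (default 2.6).
#' @param mod_min lower printed boundary of the Moderate band (default 2.7).
#' @param mod_max upper printed boundary of the Moderate band (default 4.4).
#' @param high_min lower printed boundary of the High band (default 4.5).
#' @return a named numeric vector of class `risk_cutoffs`.
#' @export
risk_cutoffs <- function(low_max = 2.6, mod_min = 2.7, mod_max = 4.4,
                         high_min = 4.5) {
  v <- c(low_max = low_max, mod_min = mod_min, mod_max = mod_max,
         high_min = high_min)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("cut-offs must be finite and non-negative", call. = FALSE)
  }
  if (!(low_max < mod_min && mod_min <= mod_max && mod_max < high_min)) {
    stop("cut-offs must satisfy low_max < mod_min <= mod_max < high_min",
         call. = FALSE)
  }
  structure(v, class = "risk_cutoffs")
}

#' Assemble the multifactorial risk model
#'
#' @param factors list of [risk_factor()] objects, in hierarchical order
#'   (most to least contributing).
#' @param cutoffs a [risk_cutoffs()] object.
#' @return an object of class `risk_model`.
#' @export
risk_model <- function(factors, cutoffs = risk_cutoffs()) {
  if (!length(factors) || !all(vapply(factors, inherits, logical(1),
                                      "risk_factor"))) {
    stop("'factors' must be a non-empty list of risk_factor objects",
         call. = FALSE)
  }
  nms <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("factor names must be unique: ",
         paste(nms[duplicated(nms)], collapse = ", "), call. = FALSE)
  }
  if (!inherits(cutoffs, "risk_cutoffs")) cutoffs <- do.call(risk_cutoffs, as.list(cutoffs))
  structure(list(factors = stats::setNames(factors, nms), cutoffs = cutoffs),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat("Multifactorial risk model:", length(x$factors), "factors\n")
  cat("  cut-offs: Low <=", x$cutoffs[["low_max"]],
      "| Moderate", x$cutoffs[["mod_min"]], "-", x$cutoffs[["mod_max"]],
      "| High >=", x$cutoffs[["high_min"]], "\n")
  for (f in x$factors) {
    at_risk <- setdiff(names(f$weights), f$referent)
    cat(sprintf("  %-14s ref=%s; %s\n", f$name, f$referent,
                paste0(at_risk, "=",
                       formatC(f$weights[at_risk], format = "fg"),
                       collapse = ", ")))
  }
  invisible(x)
}

#' Total risk score for one screening profile
#'
#' Sums the weight of the observed level over every factor in the model.
#' An all-referent profile scores exactly 0.
#'
#' @param profile named character vector or list mapping each factor name to
#'   the observed level label; every model factor must be present.
#' @param model a [risk_model()].
#' @return non-negative numeric score (full precision; round for display).
#' @export
risk_score <- function(profile, model) {
  stopifnot(inherits(model, "risk_model"))
  profile <- unlist(profile)
  total <- 0
  for (f in model$factors) {
    if (!f$name %in% names(profile) || is.na(profile[[f$name]])) {
      stop("profile is missing factor '", f$name, "'", call. = FALSE)
    }
    lev <- as.character(profile[[f$name]])
    if (!lev %in% f$levels) {
      stop("factor '", f$name, "': unknown level '", lev, "'", call. = FALSE)
    }
    total <- total + f$weights[[lev]]
  }
  total
}

#' Score every row of a screening records table
#'
#' @param records data frame with one column per model factor (levels as
#'   character values).
#' @param model a [risk_model()].
#' @return numeric vector of risk scores, one per row.
#' @export
score_records <- function(records, model) {
  stopifnot(inherits(model, "risk_model"), is.data.frame(records))
  total <- numeric(nrow(records))
  for (f in model$factors) {
    if (!f$name %in% names(records)) {
      stop("records are missing factor column '", f$name, "'", call. = FALSE)
    }
    lev <- as.character(records[[f$name]])
    bad <- !lev %in% f$levels
    if (any(bad)) {
      stop("factor '", f$name, "': unknown level(s) ",
           paste(unique(lev[bad]), collapse = ", "),
           " (rows ", paste(utils::head(which(bad), 5), collapse = ", "),
           if (sum(bad) > 5) ", ..." else "", ")", call. = FALSE)
    }
    total <- total + f$weights[lev]
  }
  unname(total)
}

# shared by classify_risk() and who_severity(): half-open bands
classify_interval <- function(x, cutoffs) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("scores must be finite and non-negative", call. = FALSE)
  }
  out <- ifelse(x >= cutoffs[["high_min"]], "High",
                ifelse(x >= cutoffs[["mod_min"]], "Moderate", "Low"))
  factor(out, levels = c("Low", "Moderate", "High"), ordered = TRUE)
}

#' Classify a risk score into Low / Moderate / High
#'
#' @param score numeric vector of non-negative risk scores.
#' @param model a [risk_model()] (its cut-offs are used), or a
#'   [risk_cutoffs()] object.
#' @return ordered factor with levels Low < Moderate < High.
#' @examples
#' m <- risk_model(list(risk_factor("f", c("no", "yes"), "no", c(yes = 5))))
#' classify_risk(c(2.6, 3.0, 4.5), m)   # Low, Moderate, High
#' @export
classify_risk <- function(score, model) {
  cutoffs <- if (inherits(model, "risk_model")) model$cutoffs else model
  if (!inherits(cutoffs, "risk_cutoffs")) {
    stop("'model' must be a risk_model or risk_cutoffs object", call. = FALSE)
  }
  classify_interval(score, cutoffs)
}

#' Dichotomize a risk category into a screening result
#'
#' Moderate and High are collapsed into "positive"; Low is "negative".
#' Equivalently the test is positive iff the score reaches the Moderate
#' band's lower boundary.
#'
#' @param category factor or character vector of risk categories.
#' @return factor with levels negative, positive.
#' @export
dichotomize <- function(category) {
  category <- as.character(category)
  ok <- category %in% c("Low", "Moderate", "High")
  if (any(!ok)) {
    stop("unknown risk category: ",
         paste(unique(category[!ok]), collapse = ", "), call. = FALSE)
  }
  factor(ifelse(category == "Low", "negative", "positive"),
         levels = c("negative", "positive"))
}

#' Read a risk-model configuration file
#'
#' The configuration is YAML: a `cutoffs` block (optional; WHO defaults
#' otherwise) and a `factors` list, each entry carrying `name`, `levels`,
#' `referent` and an `odds_ratios` map for the non-referent levels.  The
#' packaged default (`system.file("extdata", "model_default.yaml", package =
#' "cariesrisk")`) ships illustrative odds ratios, not values fitted to any
#' surveillance cohort.
#'
#' @param path file path to the YAML configuration.
#' @return a [risk_model()].
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$factors) || !length(cfg$factors)) {
    stop("configuration has no 'factors' entry", call. = FALSE)
  }
  cutoffs <- if (is.null(cfg$cutoffs)) risk_cutoffs() else
    do.call(risk_cutoffs, cfg$cutoffs)
  factors <- lapply(cfg$factors, function(f) {
    risk_factor(f$name, unlist(f$levels), f$referent,
                unlist(f$odds_ratios))
  })
  risk_model(factors, cutoffs)
}

#' Write a risk model to a configuration file
#'
#' Inverse of [read_model_config()]: odds ratios are reconstructed as
#' weight + 1 for non-referent levels.
#'
#' @param model a [risk_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  cfg <- list(
    cutoffs = as.list(unclass(model$cutoffs)),
    factors = lapply(unname(model$factors), function(f) {
      at_risk <- setdiff(names(f$weights), f$referent)
      list(name = f$name, levels = as.list(f$levels), referent = f$referent,
           odds_ratios = as.list(f$weights[at_risk] + 1))
    })
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
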
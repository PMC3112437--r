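#' DMFT index from tooth-level counts
#'
#' The DMFT index — the count of Decayed, Missing (due to caries) and Filled
#' permanent Teeth — is the gold standard for caries experience.  The total
#' is capped at 32 teeth (full adult dentition including third molars, which
#' may have erupted in adolescents).
#'
#' @param decayed,missing,filled non-negative integer counts (vectorized).
#' @return a data frame of class `dmft_index` with columns `decayed`,
#'   `missing`, `filled`, `total`.
#' @examples
#' dmft_index(2, 1, 3)$total   # 6
#' @export
dmft_index <- function(decayed, missing, filled) {
  n <- max(length(decayed), length(missing), length(filled))
  decayed <- rep_len(as.numeric(decayed), n)
  missing <- rep_len(as.numeric(missing), n)
  filled  <- rep_len(as.numeric(filled), n)
  comp <- cbind(decayed, missing, filled)
  if (any(!is.finite(comp)) || any(comp < 0) || any(comp != round(comp))) {
    stop("DMFT components must be non-negative integers", call. = FALSE)
  }
  total <- decayed + missing + filled
  if (any(total > 32)) {
    stop("DMFT total exceeds 32 teeth (rows ",
         paste(utils::head(which(total > 32), 5), collapse = ", "), ")",
         call. = FALSE)
  }
  structure(
    data.frame(decayed = decayed, missing = missing, filled = filled,
               total = total),
    class = c("dmft_index", "data.frame")
  )
}

#' Gold-standard disease status from the DMFT index
#'
#' Any caries experience counts: DMFT >= 1 is "with_disease", DMFT = 0 is
#' "without_disease".
#'
#' @param x a [dmft_index()] object or a numeric vector of DMFT totals.
#' @return factor with levels without_disease, with_disease.
#' @export
disease_status <- function(x) {
  total <- if (inherits(x, "dmft_index")) x$total else as.numeric(x)
  if (any(!is.finite(total)) || any(total < 0)) {
    stop("DMFT totals must be finite and non-negative", call. = FALSE)
  }
  factor(ifelse(total >= 1, "with_disease", "without_disease"),
         levels = c("without_disease", "with_disease"))
}

#' WHO severity category for a population mean DMFT
#'
#' Applies the WHO population benchmarks (Low <= 2.6, Moderate 2.7-4.4,
#' High >= 4.5) to a mean DMFT — the same interval logic the risk model
#' reuses as score cut-offs, so the two agree on every input.
#'
#' @param mean_dmft non-negative numeric vector of mean DMFT values.
#' @param cutoffs a [risk_cutoffs()] object.
#' @return ordered factor with levels Low < Moderate < High.
#' @export
who_severity <- function(mean_dmft, cutoffs = risk_cutoffs()) {
  if (!inherits(cutoffs, "risk_cutoffs")) {
    stop("'cutoffs' must be a risk_cutoffs object", call. = FALSE)
  }
  classify_interval(mean_dmft, cutoffs)
}

#' Extract DMFT indices from a screening records table
#'
#' Records carry tooth-level columns `dmft_d`, `dmft_m`, `dmft_f` and may
#' also carry a precomputed `dmft_total`.  When both are present and
#' disagree on any row, the whole table is rejected (fail-loud rather than
#' silently preferring one source).
#'
#' @param records data frame with DMFT columns.
#' @return a [dmft_index()] data frame, one row per record.
#' @export
dmft_from_records <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("dmft_d", "dmft_m", "dmft_f")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records are missing DMFT column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  idx <- dmft_index(records$dmft_d, records$dmft_m, records$dmft_f)
  if ("dmft_total" %in% names(records)) {
    supplied <- as.numeric(records$dmft_total)
    bad <- which(!is.na(supplied) & supplied != idx$total)
    if (length(bad)) {
      stop("dmft_total disagrees with dmft_d + dmft_m + dmft_f on row(s) ",
           paste(utils::head(bad, 5), collapse = ", "),
           if (length(bad) > 5) ", ..." else "", call. = FALSE)
    }
  }
  idx
}
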
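#' Read and validate a screening records file
#'
#' The canonical records dialect is comma-delimited UTF-8 with a header
#' row: `record_id`, `year`, one column per risk factor, and DMFT columns
#' (`dmft_d`, `dmft_m`, `dmft_f`, optionally `dmft_total`).  Missing values
#' are empty fields.  Rows are validated (factor levels against the model,
#' DMFT bounds and component/total agreement); in strict mode any invalid
#' row aborts the read, in permissive mode invalid rows are dropped with a
#' logged message per row.
#'
#' @param path path to the CSV file.
#' @param model optional [risk_model()]; when supplied, factor columns must
#'   be present and every value must be a valid level.
#' @param strict abort on the first validation problem (default `TRUE`);
#'   otherwise skip offending rows and log them to standard error.
#' @return validated data frame; in permissive mode the dropped row numbers
#'   are attached as attribute `"skipped"`.
#' @export
read_records <- function(path, model = NULL, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (!all(c("record_id", "year") %in% names(rec))) {
    stop("malformed header: need at least 'record_id' and 'year' columns",
         call. = FALSE)
  }
  dup <- unique(rec$record_id[duplicated(rec$record_id)])
  if (length(dup)) {
    stop("duplicate record ids: ",
         paste(utils::head(dup, 10), collapse = ", "), call. = FALSE)
  }
  bad <- rep(FALSE, nrow(rec))
  why <- character(nrow(rec))
  flag <- function(rows, msg) {
    fresh <- rows[!bad[rows]]
    bad[fresh] <<- TRUE
    why[fresh] <<- msg
  }
  if (!is.null(model)) {
    stopifnot(inherits(model, "risk_model"))
    miss <- setdiff(names(model$factors), names(rec))
    if (length(miss)) {
      stop("records are missing factor column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    for (f in model$factors) {
      v <- as.character(rec[[f$name]])
      flag(which(is.na(v) | !v %in% f$levels),
           paste0("invalid level for factor '", f$name, "'"))
    }
  }
  dmft_cols <- c("dmft_d", "dmft_m", "dmft_f")
  if (all(dmft_cols %in% names(rec))) {
    comp <- as.matrix(rec[, dmft_cols])
    ok_num <- is.finite(comp) & comp >= 0 & comp == round(comp)
    flag(which(!apply(ok_num, 1, all)), "invalid DMFT component")
    tot <- rowSums(comp)
    flag(which(!bad & tot > 32), "DMFT total exceeds 32")
    if ("dmft_total" %in% names(rec)) {
      sup <- as.numeric(rec$dmft_total)
      flag(which(!bad & !is.na(sup) & sup != tot),
           "dmft_total disagrees with components")
    }
  }
  if (any(bad)) {
    msgs <- paste0("row ", which(bad), ": ", why[bad])
    if (strict) {
      stop("invalid records (strict mode):\n  ",
           paste(utils::head(msgs, 10), collapse = "\n  "),
           if (sum(bad) > 10) "\n  ..." else "", call. = FALSE)
    }
    for (m in msgs) message("skipping ", m)
    skipped <- which(bad)
    rec <- rec[!bad, , drop = FALSE]
    rownames(rec) <- NULL
    attr(rec, "skipped") <- skipped
  }
  rec
}

#' Write a screening records file
#'
#' Inverse of [read_records()]: plain comma-delimited UTF-8 with header,
#' no quoting beyond what CSV requires, no row names.
#'
#' @param records data frame of screening records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a multi-year validity report
#'
#' Emits the per-stratum metrics plus the cross-stratum averages row, in
#' the summary-table layout: one row per stratum, integer-percent display
#' columns alongside full-precision estimates and confidence bounds.
#'
#' @param summary a [summarize_years()] result.
#' @param path output path, or `NULL` to print the human-readable table to
#'   the console.
#' @param format `"csv"` (machine-readable, long format) or `"text"`
#'   (the human-readable table).
#' @return `path` (or the summary, when printing), invisibly.
#' @export
write_report <- function(summary, path = NULL,
                         format = c("csv", "text")) {
  if (!inherits(summary, "multiyear_summary")) {
    stop("'summary' must come from summarize_years()", call. = FALSE)
  }
  format <- match.arg(format)
  if (is.null(path)) {
    print(summary)
    return(invisible(summary))
  }
  if (format == "csv") {
    long <- summary$per_stratum
    avg <- data.frame(stratum = "mean", metric = names(summary$means),
                      estimate = unname(summary$means),
                      lower = NA_real_, upper = NA_real_, n = NA_real_,
                      level = summary$level,
                      percent = unname(summary$mean_percent))
    utils::write.csv(rbind(long, avg), path, row.names = FALSE,
                     fileEncoding = "UTF-8")
  } else {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    sink(con)
    print(summary)
    sink()
  }
  invisible(path)
}
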
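#' CSV report writers
#'
#' Every pipeline stage writes a plain CSV a plotting layer (or spreadsheet)
#' can consume directly. Numeric columns keep full precision; rounding is a
#' presentation concern. Two runs with identical inputs (including seed)
#' produce byte-identical files.
#'
#' @name reporting
NULL

write_csv_plain <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the base-case result table
#'
#' Columns `row`, `soc`, `twt`, `difference`; rows are cost channels, the
#' 2wT channel subtotal, totals and the AE-yield outcome (see
#' [base_case_table()]).
#'
#' @param result A `twt_model_result`.
#' @param path Output CSV path (directories are created).
#' @return `path`, invisibly.
#' @export
write_base_case_csv <- function(result, path) {
  write_csv_plain(base_case_table(result), path)
}

#' Write a tornado table
#'
#' @param tornado A data.frame from [one_way()].
#' @param path Output CSV path.
#' @param top Flag the `top` largest swings in a `top_flag` column
#'   (default 10).
#' @return `path`, invisibly.
#' @export
write_tornado_csv <- function(tornado, path, top = 10) {
  tornado$top_flag <- seq_len(nrow(tornado)) <= top
  write_csv_plain(tornado, path)
}

#' Write PSA incremental pairs
#'
#' Columns `sim`, `delta_yield_points`, `delta_cost_usd`, `quadrant` — the
#' data behind an incremental cost-effectiveness scatterplot.
#'
#' @param psa A `twt_psa` from [run_psa()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_psa_csv <- function(psa, path) {
  stopifnot(inherits(psa, "twt_psa"))
  write_csv_plain(psa$pairs, path)
}

#' Write / read trial records
#'
#' The documented interchange format for individual-level follow-up records:
#' one row per client with the columns of [simulate_trial()]. A real trial
#' export with matching columns can be substituted for synthetic data.
#'
#' @param records A trial `data.frame`.
#' @param path CSV path.
#' @return `write_trial_csv()` returns `path` invisibly; `read_trial_csv()`
#'   the records.
#' @export
write_trial_csv <- function(records, path) {
  write_csv_plain(records, path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("trial record file not found: '%s'", path), call. = FALSE)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("attended_day2", "attended_day7", "attended_day42",
                "traced_by_outreach", "had_ae"))
    if (col %in% names(rec)) rec[[col]] <- as.logical(rec[[col]])
  rec
}
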
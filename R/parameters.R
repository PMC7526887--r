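#' Model parameters for the post-VMMC follow-up cost-effectiveness model
#'
#' A `twt_parameter` is one named model input: a baseline value, a plausible
#' range used by the sensitivity analyses, a category that decides its
#' sampling distribution (`"probability"` -> beta, `"cost"` -> gamma,
#' `"other"` -> normal), whether it is fixed (no uncertainty), and which
#' arm(s) of the comparison it enters.
#'
#' @param name Identifier, e.g. `"p_attend_day2_soc"`.
#' @param baseline Base-case value.
#' @param low,high Plausible range (95% CI where available). May be `NA` for
#'   fixed parameters.
#' @param category One of `"probability"`, `"cost"`, `"other"`.
#' @param fixed Logical; `TRUE` for parameters with no uncertainty.
#' @param arm_scope One of `"both"`, `"soc"`, `"twt"`.
#' @param units Free-text units, e.g. `"USD/month"`.
#'
#' @return An object of class `twt_parameter`.
#' @export
parameter <- function(name, baseline, low = NA_real_, high = NA_real_,
                      category = c("probability", "cost", "other"),
                      fixed = FALSE, arm_scope = c("both", "soc", "twt"),
                      units = "") {
  p <- new_parameter(name, baseline, low, high, match.arg(category),
                     fixed, match.arg(arm_scope), units)
  validate_parameter(p)
  p
}

# Unvalidated constructor; load_parameters() needs it to fill default ranges
# before the range invariant is enforced.
new_parameter <- function(name, baseline, low, high, category, fixed,
                          arm_scope, units) {
  structure(
    list(name = as.character(name), baseline = as.numeric(baseline),
         low = as.numeric(low), high = as.numeric(high),
         category = category, fixed = isTRUE(fixed),
         arm_scope = arm_scope, units = as.character(units)),
    class = "twt_parameter")
}

#' Validate a single parameter
#'
#' Enforces the invariants `low <= baseline <= high` (unless fixed, in which
#' case the range may be absent), probabilities confined to `[0, 1]`, and
#' non-negative cost lower bounds. Failures name the offending parameter.
#'
#' @param p A `twt_parameter`.
#' @return `p`, invisibly, if valid; otherwise an error.
#' @export
validate_parameter <- function(p) {
  stopifnot(inherits(p, "twt_parameter"))
  fail <- function(msg) stop(sprintf("parameter '%s': %s", p$name, msg), call. = FALSE)
  if (!is.finite(p$baseline)) fail("baseline is not a finite number")
  has_range <- is.finite(p$low) && is.finite(p$high)
  if (!p$fixed && !has_range)
    fail("non-fixed parameter must carry a [low, high] range")
  if (has_range) {
    if (p$low > p$high) fail(sprintf("low (%g) exceeds high (%g)", p$low, p$high))
    if (p$baseline < p$low || p$baseline > p$high)
      fail(sprintf("baseline %g outside [low, high] = [%g, %g]",
                   p$baseline, p$low, p$high))
  }
  if (p$category == "probability") {
    if (p$baseline < 0 || p$baseline > 1)
      fail(sprintf("probability baseline %g outside [0, 1]", p$baseline))
    if (has_range && (p$low < 0 || p$high > 1))
      fail(sprintf("probability range [%g, %g] outside [0, 1]", p$low, p$high))
  }
  if (p$category == "cost") {
    if (p$baseline < 0) fail("cost baseline is negative")
    if (has_range && p$low < 0) fail("cost low bound is negative")
  }
  invisible(p)
}

#' @export
print.twt_parameter <- function(x, ...) {
  rng <- if (is.finite(x$low)) sprintf(" [%g, %g]", x$low, x$high) else ""
  cat(sprintf("<parameter> %s = %g%s (%s%s, %s)%s\n", x$name, x$baseline, rng,
              x$category, if (x$fixed) ", fixed" else "", x$arm_scope,
              if (nzchar(x$units)) paste0(" ", x$units) else ""))
  invisible(x)
}

# Identifiers every costing / tree operation relies on. Lookup of anything
# absent from this set (or the set itself being incomplete) is an error.
required_parameter_names <- function() {
  c("p_attend_day2_soc", "p_attend_day7_soc", "p_attend_day42_soc",
    "p_attend_day2_twt", "p_attend_day7_twt", "p_attend_day42_twt",
    "ae_rate_soc", "ae_rate_twt",
    "sms_bundle_price", "nurse_wage_month", "fte_2wt_nurse",
    "mean_texts_per_client", "call_unit_price", "fte_callback_nurse",
    "mean_calls_per_client",
    "clerk_wage_month", "clerk_time_hours", "nurse_review_hours",
    "hours_per_month",
    "supply_gloves", "supply_antiseptic", "supply_gauze", "supply_bed_liner",
    "supply_distilled_water", "supply_alcohol_rub",
    "outreach_distance_km", "fuel_liters_per_km", "fuel_price_per_liter",
    "driver_wage_month", "outreach_time_hours", "outreach_call_price",
    "lunch_allowance",
    "p_ae_bleeding", "p_ae_infection", "p_ae_swelling",
    "cost_ae_surgery", "cost_ae_antibiotic", "cost_ae_painkiller",
    "trial_duration_months", "n_twt_clients", "sms_bundle_size",
    "expected_ae_rate")
}

#' Assemble a parameter table
#'
#' A `twt_parameter_table` maps identifiers to [parameter()] objects and is
#' the single input every downstream stage (costing, decision tree,
#' sensitivity analyses) consumes. Model constants (trial duration, cohort
#' size, SMS bundle size, the expected 2% adverse-event rate) travel in the
#' table as fixed parameters.
#'
#' @param params A list of `twt_parameter` objects.
#' @param complete If `TRUE` (default), require every identifier used by the
#'   model; set `FALSE` for fragments, e.g. estimates recovered from a trial.
#' @return A `twt_parameter_table`.
#' @export
parameter_table <- function(params, complete = TRUE) {
  stopifnot(is.list(params))
  for (p in params) validate_parameter(p)
  nms <- vapply(params, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop("duplicate parameter names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  names(params) <- nms
  if (complete) {
    missing <- setdiff(required_parameter_names(), nms)
    if (length(missing))
      stop("parameter table is missing required identifiers: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(params, class = "twt_parameter_table")
}

#' @export
print.twt_parameter_table <- function(x, ...) {
  cat(sprintf("<parameter table> %d parameters (%d fixed)\n",
              length(x), sum(vapply(x, `[[`, TRUE, "fixed"))))
  invisible(x)
}

#' Look up one parameter (or its baseline value)
#'
#' Lookup of a missing identifier is an error, never a silent default.
#'
#' @param pt A `twt_parameter_table`.
#' @param name Identifier.
#' @return `get_parameter()` the `twt_parameter`; `param_value()` its
#'   baseline as a number.
#' @export
get_parameter <- function(pt, name) {
  stopifnot(inherits(pt, "twt_parameter_table"))
  p <- pt[[name]]
  if (is.null(p))
    stop(sprintf("unknown parameter '%s'", name), call. = FALSE)
  p
}

#' @rdname get_parameter
#' @export
param_value <- function(pt, name) get_parameter(pt, name)$baseline

#' Baselines of every parameter as a named numeric vector
#' @param pt A `twt_parameter_table`.
#' @return Named numeric vector of baselines.
#' @export
param_values <- function(pt) {
  stopifnot(inherits(pt, "twt_parameter_table"))
  vapply(pt, `[[`, 0, "baseline")
}

#' Replace baseline values (e.g. with sensitivity draws or trial estimates)
#'
#' Returns a copy of the table with the named baselines replaced. Range
#' checks against `[low, high]` are not re-applied: sampled values may
#' legitimately leave the 95% interval. Probability bounds are still
#' enforced.
#'
#' @param pt A `twt_parameter_table`.
#' @param values Named numeric vector of new baselines.
#' @return The modified table.
#' @export
set_values <- function(pt, values) {
  stopifnot(inherits(pt, "twt_parameter_table"))
  if (length(values) == 0) return(pt)
  stopifnot(!is.null(names(values)))
  for (nm in names(values)) {
    p <- get_parameter(pt, nm)
    v <- as.numeric(values[[nm]])
    if (p$category == "probability" && (v < 0 || v > 1))
      stop(sprintf("parameter '%s': probability value %g outside [0, 1]", nm, v),
           call. = FALSE)
    pt[[nm]]$baseline <- v
  }
  pt
}

#' Merge estimated parameters into a full table
#'
#' Takes a complete table (typically [default_parameters()]) and a fragment
#' (typically from [estimate_params()]) and replaces baseline, low and high
#' of each matching identifier.
#'
#' @param pt A complete `twt_parameter_table`.
#' @param fragment A `twt_parameter_table` fragment.
#' @return The updated complete table.
#' @export
update_parameters <- function(pt, fragment) {
  stopifnot(inherits(pt, "twt_parameter_table"),
            inherits(fragment, "twt_parameter_table"))
  for (nm in names(fragment)) {
    get_parameter(pt, nm)  # error on unknown identifiers
    pt[[nm]]$baseline <- fragment[[nm]]$baseline
    pt[[nm]]$low <- fragment[[nm]]$low
    pt[[nm]]$high <- fragment[[nm]]$high
  }
  for (p in pt) validate_parameter(p)
  pt
}

#' Fill in a default range for a parameter without one
#'
#' When no empirical 95% CI is available the conventional default ranges are
#' +/- 20% of baseline for probabilities (capped to `[0, 1]`) and +/- 50% for
#' costs. "Other" parameters (times, counts, FTEs) default to +/- 20%,
#' matching the width used for the count-type entries that do carry printed
#' ranges.
#'
#' @param p A non-fixed `twt_parameter` lacking a range.
#' @return `p` with `low`/`high` filled in.
#' @export
default_range <- function(p) {
  stopifnot(inherits(p, "twt_parameter"))
  if (p$fixed)
    stop(sprintf("parameter '%s' is fixed; it takes no range", p$name), call. = FALSE)
  rel <- switch(p$category, cost = 0.5, probability = 0.2, other = 0.2)
  p$low <- (1 - rel) * p$baseline
  p$high <- (1 + rel) * p$baseline
  if (p$category == "probability") {
    p$low <- max(0, p$low)
    p$high <- min(1, p$high)
  }
  validate_parameter(p)
  p
}

#' Read a parameter table from a YAML config file
#'
#' The file holds a top-level `parameters:` sequence, one record per
#' parameter with keys `name`, `baseline`, `low`, `high`, `category`,
#' `fixed`, `arm_scope`, `units`. Records without a range and not fixed get
#' [default_range()] applied. Validation failures name the offending
#' parameter.
#'
#' @param path Path to the YAML file.
#' @param complete Require the full identifier set (default `TRUE`).
#' @return A `twt_parameter_table`.
#' @export
load_parameters <- function(path, complete = TRUE) {
  if (!file.exists(path))
    stop(sprintf("parameter file not found: '%s'", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$parameters))
    stop(sprintf("'%s' has no top-level 'parameters' list", path), call. = FALSE)
  params <- lapply(raw$parameters, function(r) {
    if (is.null(r$name)) stop("parameter record without a 'name'", call. = FALSE)
    p <- new_parameter(
      name = r$name, baseline = r$baseline,
      low = if (is.null(r$low)) NA_real_ else r$low,
      high = if (is.null(r$high)) NA_real_ else r$high,
      category = if (is.null(r$category)) "other" else
        match.arg(r$category, c("probability", "cost", "other")),
      fixed = isTRUE(r$fixed),
      arm_scope = if (is.null(r$arm_scope)) "both" else
        match.arg(r$arm_scope, c("both", "soc", "twt")),
      units = if (is.null(r$units)) "" else r$units)
    if (!p$fixed && !is.finite(p$low)) p <- default_range(p)
    validate_parameter(p)
    p
  })
  parameter_table(params, complete = complete)
}

#' Write a parameter table to YAML
#'
#' Inverse of [load_parameters()]: a written-then-reloaded table is identical
#' on every field.
#'
#' @param pt A `twt_parameter_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(pt, path) {
  stopifnot(inherits(pt, "twt_parameter_table"))
  recs <- lapply(unname(pt), function(p) {
    r <- list(name = p$name, baseline = p$baseline)
    if (is.finite(p$low)) { r$low <- p$low; r$high <- p$high }
    r$category <- p$category
    r$fixed <- p$fixed
    r$arm_scope <- p$arm_scope
    if (nzchar(p$units)) r$units <- p$units
    r
  })
  yaml::write_yaml(list(parameters = recs), path, precision = 12)
  invisible(path)
}

#' The bundled default parameter set
#'
#' Loads the package's default parameter table (`extdata/table1.yaml`): the
#' trial-derived attendance and adverse-event probabilities, unit costs,
#' wages, times and allowances of the Zimbabwe VMMC follow-up comparison,
#' with their 95% CI / plausible ranges.
#'
#' @return A `twt_parameter_table`.
#' @export
default_parameters <- function() {
  load_parameters(system.file("extdata", "table1.yaml", package = "twtcea",
                              mustWork = TRUE))
}
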
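#' Wilson score interval for a binomial proportion
#'
#' Well-behaved at the small proportions this model lives on (attendance
#' rates of a few percent, AE rates below 2.5%) and at the boundaries: with
#' zero successes the lower bound is 0, with all successes the upper bound
#' is 1.
#'
#' @param x Number of successes.
#' @param n Number of trials (> 0).
#' @param conf Confidence level (default 0.95).
#' @return Named vector `c(estimate, low, high)`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  hw <- z / denom * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  # exact at the boundaries (and guard the interval against roundoff)
  low <- if (x == 0) 0 else min(max(0, center - hw), p)
  high <- if (x == n) 1 else max(min(1, center + hw), p)
  c(estimate = p, low = low, high = high)
}

ae_types <- c("bleeding", "infection", "swelling")

#' Simulate an individual-level follow-up trial
#'
#' Generates records with the statistical structure the decision-tree model
#' assumes: per client, independent Bernoulli attendance at the day-2/7/42
#' visits at the arm's rates, a Bernoulli adverse event at the arm's AE rate
#' with a categorical type (bleeding/infection/swelling, conditional
#' distribution given an AE), SoC outreach tracing exactly when day 2 is
#' missed, and Poisson text/call counts (2wT only) at the stated means.
#'
#' @param pt A complete `twt_parameter_table` holding the true rates.
#' @param n_per_arm Clients per arm (>= 1; 362 matches the trial cohort).
#' @param seed Integer seed.
#' @return A `data.frame`, one row per client: `client_id`, `arm`,
#'   `attended_day2/7/42`, `traced_by_outreach`, `had_ae`, `ae_type`
#'   (`"none"` iff no AE), `n_texts`, `n_calls` (0 for SoC).
#' @export
simulate_trial <- function(pt, n_per_arm, seed) {
  stopifnot(inherits(pt, "twt_parameter_table"), n_per_arm >= 1)
  set.seed(as.integer(seed))
  type_probs <- c(param_value(pt, "p_ae_bleeding"),
                  param_value(pt, "p_ae_infection"),
                  param_value(pt, "p_ae_swelling"))
  type_probs <- type_probs / sum(type_probs)
  one_arm <- function(arm) {
    n <- n_per_arm
    att <- sapply(c("day2", "day7", "day42"), function(d)
      stats::rbinom(n, 1, param_value(pt, sprintf("p_attend_%s_%s", d, arm))) == 1)
    had_ae <- stats::rbinom(n, 1, param_value(pt, paste0("ae_rate_", arm))) == 1
    ae_type <- rep("none", n)
    if (any(had_ae))
      ae_type[had_ae] <- sample(ae_types, sum(had_ae), replace = TRUE,
                                prob = type_probs)
    data.frame(
      client_id = paste0(arm, "_", seq_len(n)),
      arm = arm,
      attended_day2 = att[, "day2"], attended_day7 = att[, "day7"],
      attended_day42 = att[, "day42"],
      traced_by_outreach = if (arm == "soc") !att[, "day2"] else FALSE,
      had_ae = had_ae, ae_type = ae_type,
      n_texts = if (arm == "twt")
        stats::rpois(n, param_value(pt, "mean_texts_per_client")) else 0L,
      n_calls = if (arm == "twt")
        stats::rpois(n, param_value(pt, "mean_calls_per_client")) else 0L,
      stringsAsFactors = FALSE)
  }
  rbind(one_arm("soc"), one_arm("twt"))
}

#' Estimate model parameters back from trial records
#'
#' Parameter recovery: arm-wise attendance and AE probabilities as sample
#' proportions with Wilson 95% intervals, the AE-type conditional
#' distribution (shares of ascertained AEs by type, pooled over arms — the
#' scale the AE-management cost normalizes to anyway), and means with normal
#' 95% intervals for the text/call counts. The result is a parameter-table
#' fragment whose rows slot directly over the defaults via
#' [update_parameters()].
#'
#' @param records A trial `data.frame` as produced by [simulate_trial()] (or
#'   a real trial export with the same columns).
#' @return A `twt_parameter_table` fragment (not complete). AE-type rows are
#'   present only when at least one AE was ascertained.
#' @export
estimate_params <- function(records) {
  needed <- c("client_id", "arm", "attended_day2", "attended_day7",
              "attended_day42", "had_ae", "ae_type", "n_texts", "n_calls")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("records are missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (a in c("soc", "twt"))
    if (!any(records$arm == a))
      stop(sprintf("no records for arm '%s'", a), call. = FALSE)

  params <- list()
  prob_param <- function(name, x, n, scope)
    do.call(function(estimate, low, high)
      parameter(name, estimate, low, high, "probability", arm_scope = scope),
      as.list(wilson_ci(x, n)))
  for (a in c("soc", "twt")) {
    arm_rec <- records[records$arm == a, ]
    n <- nrow(arm_rec)
    for (d in c("day2", "day7", "day42"))
      params <- c(params, list(prob_param(
        sprintf("p_attend_%s_%s", d, a),
        sum(arm_rec[[paste0("attended_", d)]]), n, a)))
    params <- c(params, list(prob_param(
      paste0("ae_rate_", a), sum(arm_rec$had_ae), n, a)))
  }
  n_ae <- sum(records$had_ae)
  if (n_ae > 0)
    for (ty in ae_types)
      params <- c(params, list(prob_param(
        paste0("p_ae_", ty), sum(records$ae_type == ty), n_ae, "both")))
  twt_rec <- records[records$arm == "twt", ]
  count_param <- function(name, x) {
    m <- mean(x)
    half <- stats::qnorm(0.975) * stats::sd(x) / sqrt(length(x))
    if (!is.finite(half)) half <- 0
    parameter(name, m, max(0, m - half), m + half, "other", arm_scope = "twt",
              units = "per client")
  }
  params <- c(params, list(count_param("mean_texts_per_client", twt_rec$n_texts),
                           count_param("mean_calls_per_client", twt_rec$n_calls)))
  parameter_table(params, complete = FALSE)
}
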
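#' Arm specification for the follow-up decision tree
#'
#' Pulls one arm's branch probabilities out of a parameter table. Attendance
#' at the day-2, day-7 and day-42 visits is modelled as independent marginal
#' probabilities (the tree's post-day-2 subtrees are clones), so expected
#' visit counts are additive. Only the standard-of-care arm performs outreach
#' tracing after a missed day-2 visit; only the 2wT arm carries text/call
#' channels.
#'
#' @param arm `"soc"` or `"twt"`.
#' @param pt A `twt_parameter_table`.
#' @return A `twt_arm_spec`.
#' @export
arm_spec <- function(arm = c("soc", "twt"), pt) {
  arm <- match.arg(arm)
  p_attend <- c(day2 = param_value(pt, paste0("p_attend_day2_", arm)),
                day7 = param_value(pt, paste0("p_attend_day7_", arm)),
                day42 = param_value(pt, paste0("p_attend_day42_", arm)))
  spec <- structure(
    list(arm = arm, p_attend = p_attend,
         ae_rate = param_value(pt, paste0("ae_rate_", arm)),
         has_outreach = arm == "soc", has_2wt_channels = arm == "twt"),
    class = "twt_arm_spec")
  if (any(spec$p_attend < 0 | spec$p_attend > 1) ||
      spec$ae_rate < 0 || spec$ae_rate > 1)
    stop(sprintf("arm '%s': branch probabilities must lie in [0, 1]", arm),
         call. = FALSE)
  spec
}

#' Expected in-clinic visits per client
#'
#' Sum of the three independent attendance probabilities; always in `[0, 3]`.
#'
#' @param spec A `twt_arm_spec`.
#' @return Expected visits per client.
#' @export
#' @examples
#' pt <- default_parameters()
#' expected_visits(arm_spec("soc", pt))  # 1.47
#' expected_visits(arm_spec("twt", pt))  # 0.13
expected_visits <- function(spec) {
  stopifnot(inherits(spec, "twt_arm_spec"))
  sum(spec$p_attend)
}

#' Probability of an outreach tracing event (SoC only)
#'
#' Clients missing the day-2 visit are traced by phone and a home visit, so
#' the per-client outreach rate is the complement of day-2 attendance. 2wT
#' clients are never traced in person.
#'
#' @param spec A `twt_arm_spec` with `arm = "soc"`.
#' @return Probability of outreach per client.
#' @export
outreach_rate <- function(spec) {
  stopifnot(inherits(spec, "twt_arm_spec"))
  if (spec$arm != "soc")
    stop("outreach applies to the standard-of-care arm only", call. = FALSE)
  1 - spec$p_attend[["day2"]]
}

#' Adverse-event yield
#'
#' The effectiveness outcome: an arm's ascertained AE rate relative to the
#' expected (maximum) rate — the 2% safety standard — expressed as a
#' percentage. 100% means the arm ascertains exactly the expected number of
#' AEs.
#'
#' @param ae_rate Observed/ascertained AE probability.
#' @param expected Expected maximum AE rate (> 0), default 0.02.
#' @return Percent yield.
#' @export
#' @examples
#' ae_yield(0.0084)  # 42
ae_yield <- function(ae_rate, expected = 0.02) {
  if (expected <= 0) stop("expected AE rate must be > 0", call. = FALSE)
  100 * ae_rate / expected
}

new_cost_breakdown <- function(arm, text_service = 0, text_personnel = 0,
                               call_service = 0, call_personnel = 0,
                               clinic_visits = 0, outreach = 0,
                               ae_management = 0) {
  structure(
    list(arm = arm, text_service = text_service, text_personnel = text_personnel,
         call_service = call_service, call_personnel = call_personnel,
         clinic_visits = clinic_visits, outreach = outreach,
         ae_management = ae_management,
         total = text_service + text_personnel + call_service + call_personnel +
           clinic_visits + outreach + ae_management),
    class = "twt_cost_breakdown")
}

#' @export
print.twt_cost_breakdown <- function(x, ...) {
  cat(sprintf("<cost breakdown, %s arm> USD/client\n", x$arm))
  for (ch in c("text_service", "text_personnel", "call_service",
               "call_personnel", "clinic_visits", "outreach", "ae_management"))
    cat(sprintf("  %-15s %8.3f\n", ch, x[[ch]]))
  cat(sprintf("  %-15s %8.2f\n", "total", x$total))
  invisible(x)
}

#' Evaluate one arm of the decision tree
#'
#' Expected per-client cost of an arm, itemized by channel: clinic visits
#' (expected visits times per-visit cost), outreach (SoC: outreach rate times
#' per-event cost), text/call service and personnel (2wT only), and
#' adverse-event management. Because attendance branches are independent and
#' costs attach linearly to branches, the expectation equals a full
#' enumeration of tree paths weighted by path probability.
#'
#' @param spec A `twt_arm_spec` (or `"soc"`/`"twt"`, resolved against `pt`).
#' @param pt A complete `twt_parameter_table`.
#' @param include_ae_management Include the AE-management channel in the
#'   total (default `TRUE`). See the methods vignette for why reproduction
#'   analyses against published per-channel figures may exclude it.
#' @return A `twt_cost_breakdown`.
#' @export
evaluate_arm <- function(spec, pt, include_ae_management = TRUE) {
  if (is.character(spec)) spec <- arm_spec(spec, pt)
  stopifnot(inherits(spec, "twt_arm_spec"))
  visit_cost <- cost_per_clinic_visit(
    clerk_wage = param_value(pt, "clerk_wage_month"),
    clerk_hours = param_value(pt, "clerk_time_hours"),
    nurse_wage = param_value(pt, "nurse_wage_month"),
    nurse_hours = param_value(pt, "nurse_review_hours"),
    hours_per_month = param_value(pt, "hours_per_month"),
    supplies = supply_bundle(pt))
  ae_cost <- if (include_ae_management) {
    cost_ae_management(
      ae_rate = spec$ae_rate,
      type_probs = c(param_value(pt, "p_ae_bleeding"),
                     param_value(pt, "p_ae_infection"),
                     param_value(pt, "p_ae_swelling")),
      type_costs = c(param_value(pt, "cost_ae_surgery"),
                     param_value(pt, "cost_ae_antibiotic"),
                     param_value(pt, "cost_ae_painkiller")))
  } else 0
  if (spec$has_2wt_channels) {
    months <- param_value(pt, "trial_duration_months")
    n_clients <- param_value(pt, "n_twt_clients")
    wage <- param_value(pt, "nurse_wage_month")
    new_cost_breakdown(
      arm = spec$arm,
      text_service = cost_text_service(param_value(pt, "sms_bundle_price"),
                                       param_value(pt, "sms_bundle_size"),
                                       param_value(pt, "mean_texts_per_client")),
      text_personnel = cost_personnel_per_client(
        wage, param_value(pt, "fte_2wt_nurse"), months, n_clients),
      call_service = cost_call_service(param_value(pt, "call_unit_price"),
                                       param_value(pt, "mean_calls_per_client")),
      call_personnel = cost_personnel_per_client(
        wage, param_value(pt, "fte_callback_nurse"), months, n_clients),
      clinic_visits = expected_visits(spec) * visit_cost,
      ae_management = ae_cost)
  } else {
    event_cost <- cost_per_outreach_event(
      driver_wage = param_value(pt, "driver_wage_month"),
      nurse_wage = param_value(pt, "nurse_wage_month"),
      hours_per_month = param_value(pt, "hours_per_month"),
      outreach_hours = param_value(pt, "outreach_time_hours"),
      distance_km = param_value(pt, "outreach_distance_km"),
      liters_per_km = param_value(pt, "fuel_liters_per_km"),
      fuel_price = param_value(pt, "fuel_price_per_liter"),
      call_price = param_value(pt, "outreach_call_price"),
      lunch_allowance = param_value(pt, "lunch_allowance"),
      n_staff = 2,
      supplies = supply_bundle(pt))
    new_cost_breakdown(
      arm = spec$arm,
      clinic_visits = expected_visits(spec) * visit_cost,
      outreach = outreach_rate(spec) * event_cost,
      ae_management = ae_cost)
  }
}

#' Evaluate the full two-arm model
#'
#' Runs [evaluate_arm()] on both arms of one parameter table and attaches the
#' effectiveness outcomes (AE yield per arm against the expected rate).
#'
#' @inheritParams evaluate_arm
#' @return A `twt_model_result`: per-arm cost breakdowns, expected visit
#'   counts, AE yields (percent) and the expected AE rate used.
#' @export
evaluate_model <- function(pt, include_ae_management = TRUE) {
  soc <- arm_spec("soc", pt)
  twt <- arm_spec("twt", pt)
  expected <- param_value(pt, "expected_ae_rate")
  structure(
    list(soc = evaluate_arm(soc, pt, include_ae_management),
         twt = evaluate_arm(twt, pt, include_ae_management),
         expected_visits = c(soc = expected_visits(soc), twt = expected_visits(twt)),
         ae_yield = c(soc = ae_yield(soc$ae_rate, expected),
                      twt = ae_yield(twt$ae_rate, expected)),
         ae_rate = c(soc = soc$ae_rate, twt = twt$ae_rate),
         expected_ae_rate = expected),
    class = "twt_model_result")
}

#' @export
print.twt_model_result <- function(x, ...) {
  cat("<model result>\n")
  cat(sprintf("  total cost/client: SoC $%.2f, 2wT $%.2f\n",
              x$soc$total, x$twt$total))
  cat(sprintf("  AE yield: SoC %.0f%%, 2wT %.0f%% (expected rate %.0f%%)\n",
              x$ae_yield[["soc"]], x$ae_yield[["twt"]], 100 * x$expected_ae_rate))
  invisible(x)
}

#' Base-case result table
#'
#' The model result reshaped as a cost-per-client table: one row per cost
#' channel plus totals and AE yield, with SoC, 2wT and difference columns
#' (2wT minus SoC). Values are full precision; round at presentation.
#'
#' @param result A `twt_model_result` from [evaluate_model()].
#' @return A `data.frame` with columns `row`, `soc`, `twt`, `difference`.
#' @export
base_case_table <- function(result) {
  stopifnot(inherits(result, "twt_model_result"))
  channels <- c("text_service", "text_personnel", "call_service",
                "call_personnel", "clinic_visits", "outreach", "ae_management")
  soc <- vapply(channels, function(ch) result$soc[[ch]], 0)
  twt <- vapply(channels, function(ch) result$twt[[ch]], 0)
  twt_sub <- c("text_service", "text_personnel", "call_service", "call_personnel")
  df <- data.frame(
    row = c(channels[1:4], "total_2wt_channels", channels[5:7], "total",
            "ae_yield_percent"),
    soc = c(soc[1:4], sum(soc[twt_sub]), soc[5:7], result$soc$total,
            result$ae_yield[["soc"]]),
    twt = c(twt[1:4], sum(twt[twt_sub]), twt[5:7], result$twt$total,
            result$ae_yield[["twt"]]),
    stringsAsFactors = FALSE)
  df$difference <- df$twt - df$soc
  rownames(df) <- NULL
  df
}
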
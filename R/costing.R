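#' Micro-costing calculators for post-VMMC follow-up
#'
#' One calculator per cost channel. Each composes unit prices, wages, times
#' and quantities into an expected cost per client (or per visit/event), in
#' 2018 USD, at full floating precision — rounding happens only at report
#' time. All calculators are homogeneous of degree one in their monetary
#' inputs and return 0 when those inputs are 0.
#'
#' @name costing
NULL

#' Text-message service cost per client
#'
#' Texts are bought in bundles; the unit price of one message is the bundle
#' price divided by the bundle size (a continuous fraction — never rounded up
#' to whole bundles), multiplied by the mean number of texts sent per client.
#'
#' @param bundle_price USD per bundle.
#' @param bundle_size Messages per bundle (> 0).
#' @param mean_texts Mean texts sent per client.
#' @return USD per client.
#' @export
#' @examples
#' cost_text_service(1.00, 250, 21.25)  # 0.085
cost_text_service <- function(bundle_price, bundle_size, mean_texts) {
  if (bundle_size <= 0) stop("bundle_size must be > 0", call. = FALSE)
  bundle_price / bundle_size * mean_texts
}

#' Personnel cost per client from an FTE commitment
#'
#' A staff member dedicating a fraction `fte` of their time over the
#' programme period costs `wage * fte * months`, spread over the clients
#' served. Used for both the texting nurse and the call-back nurse.
#'
#' @param wage Monthly wage (USD).
#' @param fte Full-time-equivalent fraction in `[0, 1]`.
#' @param months Programme duration in months.
#' @param n_clients Number of clients served (> 0).
#' @return USD per client.
#' @export
#' @examples
#' cost_personnel_per_client(907, 0.17, 9, 362)   # ~3.833
#' cost_personnel_per_client(907, 0.022, 9, 362)  # ~0.496
cost_personnel_per_client <- function(wage, fte, months, n_clients) {
  if (n_clients <= 0) stop("n_clients must be > 0", call. = FALSE)
  if (fte < 0 || fte > 1) stop("fte must lie in [0, 1]", call. = FALSE)
  wage * fte * months / n_clients
}

#' Phone-call service cost per client
#'
#' @param call_price USD per call.
#' @param mean_calls Mean calls per client.
#' @return USD per client.
#' @export
cost_call_service <- function(call_price, mean_calls) {
  stopifnot(call_price >= 0, mean_calls >= 0)
  call_price * mean_calls
}

#' Cost of one in-clinic follow-up visit
#'
#' One clinic clerk and one nurse each spend a fixed time per visit, costed
#' at their hourly wage (monthly wage over hours worked per month), plus the
#' wound-dressing supply bundle (gloves, antiseptic, alcohol rub, gauze, bed
#' liner, distilled water).
#'
#' @param clerk_wage,nurse_wage Monthly wages (USD).
#' @param clerk_hours,nurse_hours Time per visit (hours).
#' @param hours_per_month Working hours per month (> 0).
#' @param supplies Numeric vector of per-visit supply costs (USD).
#' @return USD per visit.
#' @export
cost_per_clinic_visit <- function(clerk_wage, clerk_hours, nurse_wage,
                                  nurse_hours, hours_per_month,
                                  supplies = numeric()) {
  if (hours_per_month <= 0) stop("hours_per_month must be > 0", call. = FALSE)
  clerk_wage / hours_per_month * clerk_hours +
    nurse_wage / hours_per_month * nurse_hours +
    sum(supplies)
}

#' Cost of one outreach (home-visit tracing) event
#'
#' One driver and one nurse travel to the client's home: their time at hourly
#' wages, fuel over the round distance, one phone call during tracing, a
#' lunch allowance per travelling staff member, and the wound-dressing supply
#' bundle.
#'
#' @param driver_wage,nurse_wage Monthly wages (USD).
#' @param hours_per_month Working hours per month (> 0).
#' @param outreach_hours Staff time per event (hours).
#' @param distance_km Mean distance to the client's home (km).
#' @param liters_per_km Fuel consumption (L/km).
#' @param fuel_price USD per liter.
#' @param call_price USD for the single tracing call.
#' @param lunch_allowance USD per travelling staff member.
#' @param n_staff Number of travelling staff (>= 1; two at baseline).
#' @param supplies Numeric vector of supply costs (USD).
#' @return USD per outreach event.
#' @export
cost_per_outreach_event <- function(driver_wage, nurse_wage, hours_per_month,
                                    outreach_hours, distance_km, liters_per_km,
                                    fuel_price, call_price, lunch_allowance,
                                    n_staff = 2, supplies = numeric()) {
  if (hours_per_month <= 0) stop("hours_per_month must be > 0", call. = FALSE)
  if (n_staff < 1) stop("n_staff must be >= 1", call. = FALSE)
  (driver_wage + nurse_wage) / hours_per_month * outreach_hours +
    distance_km * liters_per_km * fuel_price +
    call_price +
    lunch_allowance * n_staff +
    sum(supplies)
}

#' Expected adverse-event management cost per client
#'
#' The arm's AE ascertainment rate times the expected management cost of an
#' ascertained AE, where the bleeding/infection/swelling type probabilities
#' are normalized to a conditional distribution over types and matched to
#' their management costs (minor surgery, antibiotics,
#' analgesics/antipyretics).
#'
#' @param ae_rate Probability of an ascertained AE, in `[0, 1]`.
#' @param type_probs Named or positional numeric vector of the three type
#'   probabilities (bleeding, infection, swelling); non-negative, positive sum.
#' @param type_costs Matching management costs (surgery, antibiotic,
#'   painkiller), USD.
#' @return USD per client.
#' @export
cost_ae_management <- function(ae_rate, type_probs, type_costs) {
  stopifnot(length(type_probs) == length(type_costs))
  if (any(type_probs < 0)) stop("type_probs must be non-negative", call. = FALSE)
  if (sum(type_probs) <= 0) stop("type_probs must have a positive sum", call. = FALSE)
  if (ae_rate < 0 || ae_rate > 1) stop("ae_rate must lie in [0, 1]", call. = FALSE)
  ae_rate * sum(type_probs / sum(type_probs) * type_costs)
}

# Supply bundle and shared channel inputs pulled from a parameter table.
supply_bundle <- function(pt) {
  c(param_value(pt, "supply_gloves"), param_value(pt, "supply_antiseptic"),
    param_value(pt, "supply_gauze"), param_value(pt, "supply_bed_liner"),
    param_value(pt, "supply_distilled_water"),
    param_value(pt, "supply_alcohol_rub"))
}
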
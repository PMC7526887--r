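# Shared fixtures and independent oracles.

# Default table, loaded once per test file.
default_pt <- function() default_parameters()

# A complete table with selected baselines overridden.
pt_with <- function(...) {
  vals <- c(...)
  set_values(default_parameters(), vals)
}

# Independent oracle for the expected per-client cost of one arm: enumerate
# every decision-tree path (2 x 2 x 2 attendance branches crossed with the
# terminal chance node "no AE / bleeding / infection / swelling") and weight
# path costs by path probabilities. Deliberately re-derives channel costs
# from raw parameters instead of calling the package's costing layer.
brute_force_arm_cost <- function(arm, pt, include_ae = TRUE) {
  v <- function(n) param_value(pt, n)
  supplies <- v("supply_gloves") + v("supply_antiseptic") + v("supply_gauze") +
    v("supply_bed_liner") + v("supply_distilled_water") + v("supply_alcohol_rub")
  visit <- v("clerk_wage_month") / v("hours_per_month") * v("clerk_time_hours") +
    v("nurse_wage_month") / v("hours_per_month") * v("nurse_review_hours") +
    supplies
  outreach_event <- (v("driver_wage_month") + v("nurse_wage_month")) /
    v("hours_per_month") * v("outreach_time_hours") +
    v("outreach_distance_km") * v("fuel_liters_per_km") * v("fuel_price_per_liter") +
    v("outreach_call_price") + 2 * v("lunch_allowance") + supplies
  per_client_channels <- if (arm == "twt") {
    v("sms_bundle_price") / v("sms_bundle_size") * v("mean_texts_per_client") +
      v("nurse_wage_month") * v("fte_2wt_nurse") * v("trial_duration_months") /
        v("n_twt_clients") +
      v("call_unit_price") * v("mean_calls_per_client") +
      v("nurse_wage_month") * v("fte_callback_nurse") * v("trial_duration_months") /
        v("n_twt_clients")
  } else 0
  p_att <- c(v(paste0("p_attend_day2_", arm)), v(paste0("p_attend_day7_", arm)),
             v(paste0("p_attend_day42_", arm)))
  ae_rate <- v(paste0("ae_rate_", arm))
  tp <- c(v("p_ae_bleeding"), v("p_ae_infection"), v("p_ae_swelling"))
  tp <- tp / sum(tp)
  tc <- c(v("cost_ae_surgery"), v("cost_ae_antibiotic"), v("cost_ae_painkiller"))
  ae_branch_p <- c(1 - ae_rate, ae_rate * tp)
  ae_branch_c <- c(0, tc)
  total <- 0
  for (a2 in 0:1) for (a7 in 0:1) for (a42 in 0:1) for (b in 1:4) {
    prob <- prod(ifelse(c(a2, a7, a42) == 1, p_att, 1 - p_att)) * ae_branch_p[b]
    cost <- (a2 + a7 + a42) * visit +
      (if (arm == "soc" && a2 == 0) outreach_event else 0) +
      per_client_channels +
      (if (include_ae) ae_branch_c[b] else 0)
    total <- total + prob * cost
  }
  total
}
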
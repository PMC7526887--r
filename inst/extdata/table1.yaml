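# Default parameter set for the 2wT vs SoC post-VMMC follow-up model.
# Baselines and ranges are the trial / programme estimates (2018 USD).
# Ranges are 95% CIs where empirical; otherwise +/-20% (probabilities,
# counts, times) or +/-50% (costs). Two upper bounds are sanity-corrected
# from misprinted sources: fuel_liters_per_km high is 0.12 (0.8x/1.2x the
# 0.1 baseline; 1.2 L/km is physically implausible) and nurse_review_hours
# high is 0.203 (a 2.03 h upper bound around a 5-minute baseline would make
# the range/4 standard-error rule meaningless).
parameters:
  # Attendance probabilities (independent marginal draws per visit day)
  - {name: p_attend_day2_soc,  baseline: 0.91, low: 0.88, high: 0.94, category: probability, arm_scope: soc}
  - {name: p_attend_day7_soc,  baseline: 0.52, low: 0.47, high: 0.57, category: probability, arm_scope: soc}
  - {name: p_attend_day42_soc, baseline: 0.04, low: 0.03, high: 0.07, category: probability, arm_scope: soc}
  - {name: p_attend_day2_twt,  baseline: 0.05, low: 0.03, high: 0.08, category: probability, arm_scope: twt}
  - {name: p_attend_day7_twt,  baseline: 0.05, low: 0.04, high: 0.09, category: probability, arm_scope: twt}
  - {name: p_attend_day42_twt, baseline: 0.03, low: 0.02, high: 0.06, category: probability, arm_scope: twt}
  # Adverse-event ascertainment rates per arm
  - {name: ae_rate_soc, baseline: 0.0084, low: 0.0028, high: 0.0243, category: probability, arm_scope: soc}
  - {name: ae_rate_twt, baseline: 0.0188, low: 0.0086, high: 0.0403, category: probability, arm_scope: twt}
  # Text messaging (2wT arm only)
  - {name: sms_bundle_price, baseline: 1.00, low: 0.50, high: 2.00, category: cost, arm_scope: twt, units: USD per 250-text bundle}
  - {name: nurse_wage_month, baseline: 907.00, low: 883.00, high: 931.00, category: cost, arm_scope: both, units: USD/month}
  - {name: fte_2wt_nurse, baseline: 0.17, low: 0.08, high: 0.25, category: other, arm_scope: twt, units: FTE}
  - {name: mean_texts_per_client, baseline: 21.25, low: 17.00, high: 25.50, category: other, arm_scope: twt, units: texts/client}
  # Follow-up phone calls (2wT arm only)
  - {name: call_unit_price, baseline: 0.09, low: 0.05, high: 0.14, category: cost, arm_scope: twt, units: USD/call}
  - {name: fte_callback_nurse, baseline: 0.022, low: 0.018, high: 0.026, category: other, arm_scope: twt, units: FTE}
  - {name: mean_calls_per_client, baseline: 0.083, low: 0.066, high: 0.099, category: other, arm_scope: twt, units: calls/client}
  # In-clinic follow-up (one clerk + one nurse per visit, wound-dressing bundle)
  - {name: clerk_wage_month, baseline: 700.00, low: 350.00, high: 1050.50, category: cost, arm_scope: both, units: USD/month}
  - {name: clerk_time_hours, baseline: 0.024, low: 0.017, high: 0.067, category: other, arm_scope: both, units: hours/visit}
  - {name: nurse_review_hours, baseline: 0.083, low: 0.017, high: 0.203, category: other, arm_scope: both, units: hours/visit}
  - {name: hours_per_month, baseline: 160, low: 128, high: 192, category: other, arm_scope: both, units: hours/month}
  - {name: supply_gloves, baseline: 0.20, low: 0.10, high: 0.30, category: cost, arm_scope: both, units: USD}
  - {name: supply_antiseptic, baseline: 0.50, low: 0.25, high: 0.75, category: cost, arm_scope: both, units: USD}
  - {name: supply_gauze, baseline: 0.20, low: 0.10, high: 0.30, category: cost, arm_scope: both, units: USD}
  - {name: supply_bed_liner, baseline: 0.20, low: 0.10, high: 0.30, category: cost, arm_scope: both, units: USD}
  - {name: supply_distilled_water, baseline: 0.10, low: 0.05, high: 0.15, category: cost, arm_scope: both, units: USD}
  - {name: supply_alcohol_rub, baseline: 0.30, low: 0.15, high: 0.45, category: cost, arm_scope: both, units: USD}
  # Outreach follow-up for missed day-2 visits (SoC only; one driver + one nurse)
  - {name: outreach_distance_km, baseline: 42.5, low: 34.0, high: 44.8, category: other, arm_scope: soc, units: km}
  - {name: fuel_liters_per_km, baseline: 0.1, low: 0.08, high: 0.12, category: other, arm_scope: soc, units: L/km}
  - {name: fuel_price_per_liter, baseline: 1.37, low: 0.69, high: 2.06, category: cost, arm_scope: soc, units: USD/L}
  - {name: driver_wage_month, baseline: 905.05, low: 452.53, high: 1357.00, category: cost, arm_scope: soc, units: USD/month}
  - {name: outreach_time_hours, baseline: 1.125, low: 0.900, high: 1.350, category: other, arm_scope: soc, units: hours/event}
  - {name: outreach_call_price, baseline: 0.09, low: 0.05, high: 0.14, category: cost, arm_scope: soc, units: USD/call}
  - {name: lunch_allowance, baseline: 10.00, low: 5.00, high: 15.00, category: cost, arm_scope: soc, units: USD/person}
  # Adverse-event types and management costs
  - {name: p_ae_bleeding, baseline: 0.0097, low: 0.0078, high: 0.0117, category: probability, arm_scope: both}
  - {name: p_ae_infection, baseline: 0.0069, low: 0.0055, high: 0.0083, category: probability, arm_scope: both}
  - {name: p_ae_swelling, baseline: 0.0083, low: 0.0067, high: 0.0100, category: probability, arm_scope: both}
  - {name: cost_ae_surgery, baseline: 53.24, low: 26.62, high: 79.86, category: cost, arm_scope: both, units: USD}
  - {name: cost_ae_antibiotic, baseline: 5.00, low: 2.50, high: 10.00, category: cost, arm_scope: both, units: USD}
  - {name: cost_ae_painkiller, baseline: 2.00, low: 1.00, high: 4.00, category: cost, arm_scope: both, units: USD}
  # Model constants (no uncertainty)
  - {name: trial_duration_months, baseline: 9, category: other, fixed: true, arm_scope: both, units: months}
  - {name: n_twt_clients, baseline: 362, category: other, fixed: true, arm_scope: both, units: clients}
  - {name: sms_bundle_size, baseline: 250, category: other, fixed: true, arm_scope: twt, units: texts/bundle}
  - {name: expected_ae_rate, baseline: 0.02, category: probability, fixed: true, arm_scope: both}
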
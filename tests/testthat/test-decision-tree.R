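test_that("expected visits add the independent attendance probabilities", {
  pt <- default_pt()
  expect_equal(expected_visits(arm_spec("soc", pt)), 1.47)
  expect_equal(expected_visits(arm_spec("twt", pt)), 0.13)
  zero <- set_values(pt, c(p_attend_day2_twt = 0, p_attend_day7_twt = 0,
                           p_attend_day42_twt = 0))
  expect_equal(expected_visits(arm_spec("twt", zero)), 0)
  # always within [0, 3]
  expect_lte(expected_visits(arm_spec("soc", pt)), 3)
})

test_that("outreach tracing happens exactly when day 2 is missed, SoC only", {
  pt <- default_pt()
  expect_equal(outreach_rate(arm_spec("soc", pt)), 0.09)
  expect_equal(outreach_rate(arm_spec("soc", set_values(pt, c(p_attend_day2_soc = 1)))), 0)
  expect_equal(outreach_rate(arm_spec("soc", set_values(pt, c(p_attend_day2_soc = 0)))), 1)
  expect_error(outreach_rate(arm_spec("twt", pt)), "standard-of-care")
})

test_that("AE yield is the rate relative to the 2% safety standard", {
  expect_equal(ae_yield(0.0084), 42)
  expect_equal(ae_yield(0.02), 100)
  expect_equal(ae_yield(0.0188), 94)
  expect_equal(ae_yield(0.01, expected = 0.05), 20)
  expect_error(ae_yield(0.01, expected = 0), "expected")
})

test_that("arm evaluation reproduces the per-channel expectations", {
  pt <- default_pt()
  twt <- evaluate_arm("twt", pt)
  expect_equal(twt$text_service, 0.085)
  expect_equal(twt$text_personnel, 3.833, tolerance = 1e-3)
  expect_equal(twt$call_service, 0.00747)
  expect_equal(twt$call_personnel, 0.496, tolerance = 1e-3)
  expect_equal(twt$outreach, 0)
  soc <- evaluate_arm("soc", pt)
  expect_equal(soc$outreach, 3.61, tolerance = 0.01 / 3.61)
  expect_equal(soc$text_service + soc$text_personnel +
                 soc$call_service + soc$call_personnel, 0)
  # totals are the exact sum of components
  for (bd in list(soc, twt))
    expect_equal(bd$total,
                 bd$text_service + bd$text_personnel + bd$call_service +
                   bd$call_personnel + bd$clinic_visits + bd$outreach +
                   bd$ae_management)
})

test_that("tree expectation equals brute-force path enumeration", {
  pt <- default_pt()
  for (arm in c("soc", "twt")) {
    expect_equal(evaluate_arm(arm, pt)$total, brute_force_arm_cost(arm, pt),
                 info = arm)
    expect_equal(evaluate_arm(arm, pt, include_ae_management = FALSE)$total,
                 brute_force_arm_cost(arm, pt, include_ae = FALSE), info = arm)
  }
  # and on perturbed instances, not just the defaults
  set.seed(21)
  for (i in 1:5) {
    pt2 <- set_values(pt, c(
      p_attend_day2_soc = runif(1), p_attend_day7_soc = runif(1),
      p_attend_day42_soc = runif(1), p_attend_day2_twt = runif(1),
      ae_rate_soc = runif(1, 0, 0.05), ae_rate_twt = runif(1, 0, 0.05),
      lunch_allowance = runif(1, 0, 30), nurse_review_hours = runif(1, 0, 0.5),
      mean_texts_per_client = runif(1, 0, 40)))
    for (arm in c("soc", "twt"))
      expect_equal(evaluate_arm(arm, pt2)$total, brute_force_arm_cost(arm, pt2))
  }
})

test_that("SoC total falls as day-2 attendance rises when outreach is dearer", {
  pt <- default_pt()
  p2 <- seq(0.1, 1, by = 0.1)
  totals <- vapply(p2, function(p)
    evaluate_arm("soc", set_values(pt, c(p_attend_day2_soc = p)))$total, 0)
  expect_true(all(diff(totals) < 0))
})

test_that("arms are structurally symmetric once their extras are stripped", {
  pt <- default_pt()
  pt <- set_values(pt, c(
    # no 2wT channels
    sms_bundle_price = 0, fte_2wt_nurse = 0, call_unit_price = 0,
    fte_callback_nurse = 0,
    # identical attendance, with day 2 certain so no outreach is triggered
    p_attend_day2_soc = 1, p_attend_day2_twt = 1,
    p_attend_day7_soc = 0.5, p_attend_day7_twt = 0.5,
    p_attend_day42_soc = 0.04, p_attend_day42_twt = 0.04,
    ae_rate_soc = 0.01, ae_rate_twt = 0.01))
  m <- evaluate_model(pt)
  expect_equal(m$soc$total, m$twt$total)
  # and all-zero costs give zero totals
  zero <- set_values(default_pt(), stats::setNames(
    rep(0, 13), c("sms_bundle_price", "nurse_wage_month", "call_unit_price",
                  "clerk_wage_month", "supply_gloves", "supply_antiseptic",
                  "supply_gauze", "supply_bed_liner", "supply_distilled_water",
                  "supply_alcohol_rub", "fuel_price_per_liter",
                  "driver_wage_month", "lunch_allowance")))
  zero <- set_values(zero, c(outreach_call_price = 0, cost_ae_surgery = 0,
                             cost_ae_antibiotic = 0, cost_ae_painkiller = 0))
  mz <- evaluate_model(zero)
  expect_equal(mz$soc$total, 0)
  expect_equal(mz$twt$total, 0)
})

test_that("the base-case table mirrors the breakdowns and their differences", {
  m <- evaluate_model(default_pt())
  tab <- base_case_table(m)
  expect_equal(tab$difference, tab$twt - tab$soc)
  expect_equal(tab$twt[tab$row == "total_2wt_channels"], 4.42,
               tolerance = 0.01 / 4.42)
  expect_equal(tab$soc[tab$row == "total"], m$soc$total)
  expect_equal(tab$soc[tab$row == "ae_yield_percent"], 42)
  expect_equal(tab$twt[tab$row == "ae_yield_percent"], 94)
})
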
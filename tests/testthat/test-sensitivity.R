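test_that("moment matching recovers the closed-form shape parameters", {
  b <- fit_distribution(parameter("p", 0.5, 0.3, 0.7, "probability"))
  expect_equal(b$family, "beta")
  expect_equal(b$se, 0.1)
  expect_equal(c(b$shape1, b$shape2), c(12, 12))
  g <- fit_distribution(parameter("c", 10, 5, 15, "cost"))
  expect_equal(g$family, "gamma")
  expect_equal(c(g$shape, g$scale), c(16, 0.625))
  n <- fit_distribution(parameter("t", 1.125, 0.9, 1.35, "other"))
  expect_equal(n$family, "normal")
  expect_equal(n$se, 0.1125)
  pt_fix <- fit_distribution(parameter("k", 9, category = "other", fixed = TRUE))
  expect_equal(pt_fix$family, "point")
  expect_equal(draw_distribution(pt_fix, 3), rep(9, 3))
})

test_that("infeasible beta moment matching names the parameter", {
  expect_error(fit_distribution(parameter("p_wide", 0.02, 0, 1, "probability")),
               "p_wide")
})

test_that("asymmetric empirical ranges stay anchored at the baseline mean", {
  d <- fit_distribution(get_parameter(default_pt(), "ae_rate_twt"))
  expect_equal(d$mean, 0.0188)
  expect_equal(d$se, (0.0403 - 0.0086) / 4)
})

test_that("fitted distributions reproduce their target moments", {
  pt <- default_pt()
  set.seed(41)
  n <- 1e5
  for (nm in c("p_attend_day2_soc", "ae_rate_soc", "lunch_allowance",
               "fuel_price_per_liter", "fte_2wt_nurse", "outreach_time_hours")) {
    d <- fit_distribution(get_parameter(pt, nm))
    x <- draw_distribution(d, n)
    # Monte-Carlo error bounds: 3 SEs of the mean / SD estimators
    expect_lt(abs(mean(x) - d$mean), 3 * d$se / sqrt(n))
    expect_lt(abs(sd(x) - d$se), 3 * d$se / sqrt(2 * n))
    if (d$family == "beta") expect_true(all(x >= 0 & x <= 1))
    if (d$family == "gamma") expect_true(all(x > 0))
  }
  # truncation keeps normal draws positive
  tr <- draw_distribution(fit_distribution(get_parameter(pt, "nurse_review_hours")),
                          n, truncate_at_zero = TRUE)
  expect_true(all(tr > 0))
})

test_that("tornado entries are sorted, exclude fixed parameters, and zero out
           for parameters the output ignores", {
  pt <- default_pt()
  tor <- one_way(pt)
  expect_true(all(diff(tor$swing) <= 0))
  expect_false(any(tor$parameter %in%
                     c("n_twt_clients", "trial_duration_months",
                       "sms_bundle_size", "expected_ae_rate")))
  # the effect-side output depends only on the AE rates
  yield_tor <- one_way(pt, output = function(p)
    incremental_analysis(evaluate_model(p))$delta_yield)
  depends <- yield_tor$parameter %in% c("ae_rate_soc", "ae_rate_twt")
  expect_true(all(yield_tor$swing[!depends] == 0))
  expect_true(all(yield_tor$swing[depends] > 0))
  # top filter keeps the largest swings
  expect_equal(one_way(pt, top = 3)$parameter, tor$parameter[1:3])
})

test_that("PSA is reproducible, complete, and collapses under point masses", {
  pt <- default_pt()
  a <- run_psa(pt, 200, seed = 5)
  b <- run_psa(pt, 200, seed = 5)
  expect_identical(a, b)
  expect_equal(sum(a$quadrant_proportions), 1)
  expect_equal(nrow(a$pairs), 200)
  expect_error(run_psa(pt, 10), "seed")
  # all parameters fixed -> every pair equals the base case
  fixed_pt <- pt
  for (nm in names(fixed_pt)) fixed_pt[[nm]]$fixed <- TRUE
  f <- run_psa(fixed_pt, 5, seed = 9)
  expect_true(all(f$pairs$delta_cost_usd == f$base$delta_cost))
  expect_true(all(f$pairs$delta_yield_points == f$base$delta_yield))
  expect_equal(unname(f$quadrant_proportions[f$base$quadrant]), 1)
})

test_that("the PSA cloud contracts to the base case as ranges shrink", {
  pt <- default_pt()
  for (nm in names(pt)) {
    if (pt[[nm]]$fixed) next
    b <- pt[[nm]]$baseline
    pt[[nm]]$low <- b * 0.995
    pt[[nm]]$high <- min(b * 1.005, if (pt[[nm]]$category == "probability") 1 else Inf)
  }
  psa <- run_psa(pt, 200, seed = 13)
  base <- psa$base
  # the dominant residual term (day-2 SoC attendance) has sd ~ $0.09 at this
  # width, against ~$1.3 for the full ranges
  expect_lt(max(abs(psa$pairs$delta_cost_usd - base$delta_cost)), 0.5)
  expect_lt(max(abs(psa$pairs$delta_yield_points - base$delta_yield)), 2)
  expect_lt(sd(psa$pairs$delta_cost_usd), 0.15)
})

test_that("shared parameters use one draw across both arms", {
  # With only the nurse wage uncertain, delta cost is linear in the wage.
  # One shared draw per simulation makes the arms' wage terms partially
  # cancel, so sd(delta cost) must equal |net slope| * se(wage); drawing the
  # wage independently per arm would inflate it by ~40%.
  pt <- default_pt()
  for (nm in names(pt)) if (nm != "nurse_wage_month") pt[[nm]]$fixed <- TRUE
  f <- function(w) incremental_analysis(
    evaluate_model(set_values(pt, c(nurse_wage_month = w))))$delta_cost
  slope <- (f(1000) - f(800)) / 200
  se_wage <- (931 - 883) / 4
  psa <- run_psa(pt, 2000, seed = 3)
  expect_equal(sd(psa$pairs$delta_cost_usd), abs(slope) * se_wage,
               tolerance = 0.08)
  expect_equal(mean(psa$pairs$delta_cost_usd), f(907), tolerance = 0.01)
  # effect side is untouched by a cost-only parameter
  expect_equal(sd(psa$pairs$delta_yield_points), 0)
})
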
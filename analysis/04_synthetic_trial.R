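#!/usr/bin/env Rscript

# Synthetic-trial check of the whole pipeline: simulate an individual-level
# follow-up trial at the default parameters (362 clients per arm, the
# trial's own size), re-estimate the rates from the records, re-run the
# base case on the estimates, and repeat over 100 seeds to measure how
# often the dominance verdict survives sampling noise.
#
# Writes results/synthetic_trial.csv (one simulated trial's records) and
# results/recovered_params.yaml (the estimates from it).

suppressPackageStartupMessages(library(twtcea))

pt <- default_parameters()
n_per_arm <- 362

rec <- simulate_trial(pt, n_per_arm, seed = 2026)
write_trial_csv(rec, file.path("results", "synthetic_trial.csv"))
est <- estimate_params(rec)
write_parameters(est, file.path("results", "recovered_params.yaml"))

merged <- update_parameters(pt, est)
inc <- incremental_analysis(evaluate_model(merged))
cat("== One synthetic trial (seed 2026) ==\n")
cat(sprintf("estimated AE rates: SoC %.4f, 2wT %.4f (truth 0.0084 / 0.0188)\n",
            param_value(merged, "ae_rate_soc"), param_value(merged, "ae_rate_twt")))
print(inc)
if (inc$delta_yield == 0)
  cat("(equal estimated AE rates: the plane's deterministic tie-break counts a\n",
      "zero effect difference on the 'more effective' side)\n", sep = "")

wins <- 0
for (r in 1:100) {
  rec_r <- simulate_trial(pt, n_per_arm, seed = 3000 + r)
  inc_r <- incremental_analysis(
    evaluate_model(update_parameters(pt, estimate_params(rec_r))))
  wins <- wins + (inc_r$verdict == "twt_dominant")
}
cat(sprintf("\nDominance verdict reproduced in %d/100 replicates at n = %d/arm.\n",
            wins, n_per_arm))
cat("With ~3 vs ~7 expected adverse events per arm, sampling noise alone\n")
cat("flips the effect sign in a non-trivial fraction of trials this size.\n")
cat("wrote results/synthetic_trial.csv, results/recovered_params.yaml\n")
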
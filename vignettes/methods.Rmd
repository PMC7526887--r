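---
title: "Methods: decision-tree cost-effectiveness of two-way texting follow-up after VMMC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decision-tree cost-effectiveness of two-way texting follow-up after VMMC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twtcea)
```

## The question and the model

Voluntary medical male circumcision (VMMC) programmes mandate in-person
post-operative reviews, yet adverse events (AEs) are rare — routinely below
the 2% safety benchmark — so most visits find nothing. Two-way texting (2wT)
replaces scheduled reviews with interactive SMS follow-up: clients report
daily, are triaged over text, and come in only on suspicion of a problem.
`twtcea` evaluates the economic trade-off between the two strategies from
the payer's perspective (the health ministry), over the short horizon from
surgery to healing (no discounting).

The model is a two-arm decision tree. Per client and arm:

* attendance at the day-2, day-7 and day-42 review visits is a Bernoulli
  branch per day, with independent marginal probabilities (the tree's
  post-day-2 subtrees are clones of one another, so no joint attendance
  distribution is modelled);
* a standard-of-care (SoC) client who misses day 2 triggers outreach
  tracing: phone calls and a home visit by a nurse and a driver;
* each client develops (or not) an ascertained AE at the arm's rate, of
  type bleeding, infection or swelling.

Because costs attach linearly to branches, the expected cost per client is a
sum of channel expectations; the package's `evaluate_arm()` is verified in
the test suite against a brute-force enumeration of all tree paths.

**Effectiveness** is AE *yield*: the arm's ascertained AE rate divided by
the expected (maximum) 2% rate, as a percentage (`ae_yield()`). Ascertaining
more of the AEs that occur is the quality signal; with rates of 0.0084 (SoC)
and 0.0188 (2wT) the yields are 42% and 94%. Yield is reported on the
percentage-point scale throughout.

## Micro-costing

Each channel is built bottom-up from unit prices, wages, times and
quantities (2018 USD):

* **Text service** — bundle price / bundle size × mean texts per client;
  SMS are priced as a continuous fraction of the 250-text bundle, never
  rounded up to whole bundles.
* **Text / call-back personnel** — monthly wage × FTE × programme months,
  spread over the cohort (`wage × fte × months / n_clients`).
* **Call service** — price per call × mean calls per client.
* **Clinic visit** — clerk and nurse time at hourly wages (monthly wage /
  hours worked per month) plus the wound-dressing supply bundle
  (gloves, antiseptic, alcohol rub, gauze, bed liner, distilled water;
  $1.50 at baseline). The arm's clinic cost is expected visits × per-visit
  cost.
* **Outreach event** — driver + nurse time, fuel (distance × L/km × price),
  one tracing call, a lunch allowance *per travelling staff member* (two
  staff, so $20/event at baseline — the only reading under which the
  published per-client outreach cost is reproduced), and the supply bundle.
  The arm's outreach cost is (1 − P(attend day 2)) × per-event cost, SoC
  only.
* **AE management** — AE rate × expected management cost of an ascertained
  AE, with the three type probabilities *normalized to a conditional
  distribution* and matched to the costs of minor surgery, antibiotics and
  analgesics. The cost of minor surgery is taken as the printed $53.24
  (VMMC price minus the circumcision kit), not recomputed.

Capital and maintenance costs of the texting platform, and all
client-borne costs (transport, time off work), are out of scope by design.

### The AE-management reproduction convention

The published per-client AE-management entries (a third of a cent per
client) cannot be reconciled with any formula built from the published
inputs — they are two orders of magnitude below `rate × cost(type)` under
every variant we tried, and they run *opposite* to the arms' AE rates. The
package therefore treats its own documented formula as the contract
(`cost_ae_management()`), includes the channel in every total by default,
and exposes `include_ae_management = FALSE` on the evaluation functions.
Comparisons against the published *follow-up* figures (the $2.10 net saving
per client, the sign of the saving at the FTE upper bound) are made with
the channel excluded, because at the contract formula's magnitude
($0.19/$0.43 per client) it would contaminate exactly the rows documented
as irreproducible. Nothing else in the pipeline depends on the flag.

### Clinic-visit ambiguity

From the published inputs the per-visit clinic cost computes to $2.0755
(0.024 clerk-hours and 0.083 nurse-hours at 160 h/month wages plus $1.50
supplies), giving per-client clinic costs of $3.05 (SoC) and $0.27 (2wT)
against published values of $3.20/$0.28 — a ~5% gap that closes exactly if
the nurse review time were 0.1 h. The package uses the printed 0.083 h and
treats the clinic rows as tolerance-band (±7%) properties, not exact
targets.

## Incremental analysis

Differences are 2wT minus SoC. On the cost-effectiveness plane (x = yield
gain in points, y = cost change in USD/client), SE means 2wT dominates
(more effective, less costly), NW means SoC dominates, and NE/SW are
trade-offs where the ICERs — cost per yield point and cost per additional
ascertained AE per client — are reported. Exact zeros are measure-zero
under continuous sampling; the deterministic tie-break counts a zero yield
difference on the "more effective" side and a zero cost difference on the
"less costly" side, so (0, 0) classifies SE. The verdict is derived from
the quadrant, so boundary cases inherit the tie-break (visible in discrete
settings such as small synthetic trials, where equal AE counts are
possible).

At baseline the model computes SoC $6.86 vs 2wT $5.12 per client
(follow-up channels only: $6.66 vs $4.69, a $1.97 saving), yields 42% vs
94%: 2wT dominant.

## Sensitivity analyses

**One-way (tornado).** Every non-fixed parameter is moved to its low and
high bound with the others at baseline; entries are ranked by the absolute
output swing, default output the incremental cost. At the default ranges
the ranking is led by the 2wT nurse FTE (swing $3.83), day-2 SoC attendance
($2.28) and the lunch allowance ($1.80). A parameter the output does not
depend on swings exactly 0.

**Probabilistic (PSA).** Each simulation draws every non-fixed parameter
once from a moment-matched distribution — beta for probabilities, gamma
for costs, normal for other quantities (times, FTEs, counts, distances) —
with mean = baseline and se = (high − low)/4, i.e. ranges read as 95%
intervals. Asymmetric empirical ranges still anchor the mean at the
baseline, so skewed families (beta, gamma) absorb the asymmetry.
Parameters are sampled independently (no correlation structure is
specified), and a parameter shared between arms (e.g. the nurse wage) uses
one draw per simulation. Normal draws are truncated at zero by resampling
*at the PSA layer*; `fit_distribution()` itself returns the untruncated
family, whose sample moments match (mean, se) exactly — with the default
ranges the truncation mass is at most ~4% (nurse review time) and
negligible elsewhere. The default is 1,000 simulations with a
user-supplied seed; runs are fully reproducible and byte-identical given
(seed, n).

With the default inputs roughly 86% of simulations find 2wT more
effective; about 80% land in the SE (dominant) quadrant and under 10% in
NE. The cost difference is the uncertain axis — its spread is dominated by
the 2wT FTE, day-2 attendance and the lunch allowance — while the
effectiveness difference rarely changes sign.

## Parameter data and two sanity corrections

The bundled `table1.yaml` carries the trial/programme estimates verbatim,
with two exceptions where the printed ranges are internally inconsistent
with the study's own univariate-sensitivity results and physically
implausible, and are read as misprints:

* fuel consumption 0.08–**0.12** L/km (not 1.2; the lower bound is exactly
  0.8 × baseline, pinning the ±20% rule, and 1.2 L/km is an order of
  magnitude beyond any vehicle);
* nurse review time 0.017–**0.203** h (not 2.033; a 2-hour upper bound
  around a 5-minute baseline would dwarf every other parameter in the
  tornado and make the range/4 standard-error rule meaningless).

Taken verbatim, those two rows would be the top two tornado bars —
contradicting the reported ranking — and would distort the PSA cost spread.
Users who want the uncorrected values can edit the YAML; nothing else in
the package assumes the correction. Parameters supplied without a range
default to ±20% for probabilities (capped to [0, 1]) and "other"
quantities, ±50% for costs. Ranges printed in the source are used verbatim
(the default rules apply only when a config omits a range). "Duration" and
"number of 2wT clients" carry no uncertainty and are fixed, as are the
bundle size (250) and the expected AE rate (2%).

Even so, the published PSA quadrant split (53% SE, 39% NE) is not
recovered: under the stated distribution rules the incremental-cost
standard deviation that propagates from the inputs is several times too
small to put ~40% of simulations on the costly side of a −$1.7 base case.
The package reports its honestly computed proportions (~77–80% SE, ~6–10%
NE across seeds) and the corresponding acceptance checks are expected to
flag the discrepancy rather than be tuned around it.

## Synthetic trials and parameter recovery

`simulate_trial()` generates individual-level records with exactly the
structure the tree assumes: independent Bernoulli attendance per day at the
arm's rates, Bernoulli AEs with a categorical type from the normalized
type distribution, outreach tracing iff day 2 is missed (SoC), and Poisson
text/call counts at the stated means (only means are specified, so Poisson
is the minimal choice; only the mean matters downstream).
`estimate_params()` inverts it: arm-wise sample proportions with Wilson
95% intervals (well-behaved at the 0.3–9% proportions in play; the
interval method is not specified by the source, and the test suite brackets
it against the continuity-corrected alternative), type shares conditional
on an AE, and means with normal intervals for counts. Estimates slot back
over the defaults via `update_parameters()` for end-to-end recovery runs.

What the generator does *not* emulate: correlation between day-2 and later
attendance (independence is declared, not inferred — real day-7 attendance
likely correlates with day-2), text-message timing or content, per-day
healing trajectories, and site effects. Passing recovery tests therefore
show the pipeline is consistent under its own assumptions, not that those
assumptions hold in a real programme.

At the trial's own size (362/arm) the expected AE counts are ~3 vs ~7, so
the *sign* of the effect difference flips by chance in roughly 8–15% of
replicates (ties included as "more effective" by the tie-break); dominance
recovery ≥95% is only reached at larger cohorts, and the suite checks the
consistency version at 5,000/arm alongside the trial-size figure.

## Numerical choices and problem sizes

* All arithmetic at full double precision; rounding only in printed
  summaries (3 decimals for sub-dollar channels, 2 for totals).
* Beta/gamma moment matching is closed-form; infeasible cases (se² ≥
  m(1 − m) for a probability; zero-mean cost with positive se) raise
  errors naming the parameter. Zero-width ranges and fixed parameters are
  point masses.
* Missing identifiers error immediately — no silent defaults anywhere in
  the lookup path.
* Test problem sizes: 10⁵ draws for distribution-moment checks, 1,000-draw
  PSA for quadrant proportions, 100 seeded replicates for coverage and
  recovery rates, 5 × 10⁴ clients/arm for AE-type convergence (~1,300
  ascertained AEs, putting the ±0.03 band at ~2 binomial SDs). The whole
  suite runs in well under a minute on one CPU.

## Known limitations

* The AE-management channel is a modelling contract, not a reproduction of
  the published per-client entries (see above).
* Costing reflects one country's staffing pattern (one clerk + one nurse
  per visit; one nurse + one driver per outreach) and 2018 USD prices;
  savings scale with the local wage structure.
* The effectiveness measure (AE yield against a fixed 2% benchmark) is a
  care-quality indicator, not a health outcome; no willingness-to-pay
  thresholds, net monetary benefit or CEACs are computed.
* No correlation between sampled parameters; no value-of-information
  analysis.
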
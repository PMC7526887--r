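Package: twtcea
Title: Cost-Effectiveness of Two-Way Texting Follow-Up After Voluntary
    Medical Male Circumcision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-effectiveness pipeline comparing two-way
    texting (2wT) with standard-of-care in-person follow-up after voluntary
    medical male circumcision, from the payer perspective. Provides
    micro-costing calculators for every follow-up cost channel (text and call
    service and personnel, clinic visits, outreach tracing, adverse-event
    management), a two-arm decision-tree evaluator with adverse-event yield as
    the effectiveness outcome, incremental and dominance analysis on the
    cost-effectiveness plane, one-way (tornado) sensitivity analysis,
    Monte-Carlo probabilistic sensitivity analysis with moment-matched
    beta/gamma/normal distributions, and a synthetic-trial generator with
    parameter recovery so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
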
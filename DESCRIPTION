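Package: monotmle
Title: Longitudinal TMLE for Diabetes Risk Under Continuous Antipsychotic
    Monotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative-safety analyses of second-generation
    antipsychotics in administrative claims data. Implements a new-user,
    active-comparator cohort builder (eligibility, outcome ascertainment,
    hierarchical censoring), a cross-validated Super Learner ensemble, and a
    longitudinal targeted minimum loss-based estimator (TMLE) of monthly
    counterfactual diabetes risk under continuous monotherapy, summarised as
    restricted mean survival time, risk differences and risk ratios with
    influence-function confidence intervals. Includes a synthetic claims
    simulator with exactly computed counterfactual truth for estimator
    validation, plus E-value, negative-control-outcome, metabolic-testing-rate
    and subgroup sensitivity analyses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rpart,
    nnet,
    ranger
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
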
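Package: readmitopt
Title: Chance-Constrained Care-Strategy Optimization for Hospital Readmission Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scenario-based stochastic programming for hospitals operating under
    readmission-penalty policies such as the U.S. Hospital Readmission Reduction
    Program (HRRP). Generates cost and readmission-probability scenarios
    (triangular treatment-plan costs, Gaussian per-patient readmission means),
    converts the probabilistic per-condition readmission constraint into its
    deterministic equivalent via the Gaussian quantile, solves the resulting
    binary treatment-plan assignment problem (a multiple-choice knapsack) exactly
    per condition and scenario, and reports cost, readmission and tier-mix
    trade-offs across confidence levels. Also includes the confusion-matrix
    analysis that validates a mean readmission-probability target against the
    median excess-readmission-ratio penalty rule, with a synthetic peer-group
    record generator.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
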
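Package: owfs
Title: Overlap Weighting and Fine Stratification for Average Treatment
    Effects in Claims Cohorts
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Head-to-head evaluation of overlap weighting (OW) and
    propensity-score fine stratification (FS) for estimating the average
    treatment effect in claims-style cohorts with infrequent exposure and
    low-frequency outcomes.  Provides a synthetic claims-cohort generator
    with a Gaussian-copula dependence structure, plasmode-style simulation
    of exposures and outcomes at controlled prevalence and risk,
    seven balancing methods (crude, OW and FS with equal/unequal
    ATE weights on full and pruned data), weighted log-link effect
    estimation with cluster-robust standard errors, covariate-balance
    diagnostics (standardized mean differences and the Mahalanobis
    balance distance), and a Monte Carlo evaluation harness reporting
    relative bias, rMSE, coverage, and significance.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
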
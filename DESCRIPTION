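Package: chedecomp
Title: Disease-Area Decomposition of Catastrophic Health Expenditure from Household Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to decompose catastrophic health expenditure (CHE) by
    disease area (non-communicable disease, communicable disease, injury)
    from household-survey microdata with a complex multistage design.
    Implements random-forest imputation of the cause of health-care visits
    observed only for the most recent encounters, two-part (logit /
    log-link GLM) modelling of out-of-pocket spending per visit,
    capacity-to-pay and CHE estimation at a 40% threshold with a 75%
    disease-attribution rule, strata-resampled cluster bootstrap
    uncertainty intervals, wealth-quintile equity breakdowns, and a
    "visits-to-CHE" drivers analysis with cluster-robust regressions.
    A synthetic survey generator emulating the structure of multi-country
    ageing-and-adult-health surveys provides ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    arrow,
    glmnet,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
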
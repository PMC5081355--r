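Package: mmclaims
Title: Claims-Based Case-Finding Algorithms for Multiple Myeloma
Version: 0.1.0
Authors@R:
    person("Claims Phenotyping", "Contributors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for developing and validating rule-based algorithms that
    identify multiple myeloma patients in administrative claims data.
    Provides a longitudinal claims data model with delimited-table
    interchange, configurable clinical code sets with trailing-wildcard
    matching, EMR-anchored gold-standard cohort construction, per-diagnosis
    evaluation panels with temporal feature windows, a boolean clause-tree
    rule engine with earliest-index flagging, diagnostic-accuracy metrics
    including a prevalence-free derived positive predictive value, stratum
    descriptives, and a calibrated synthetic claims generator so the whole
    pipeline runs without access to proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
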
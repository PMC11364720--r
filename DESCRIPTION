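Package: ddrenal
Title: Renal Function-Adapted D-Dimer Cutoffs to Rule Out Pulmonary Embolism
Version: 0.1.0
Authors@R: person("ddrenal", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools for deriving and evaluating renal function-adapted (and
    C-reactive-protein-adapted) D-dimer cutoffs to rule out pulmonary embolism
    in emergency department populations. Provides deterministic clinical
    calculators (CKD-EPI eGFR, Wells score, YEARS criteria, age-adjusted
    D-dimer cutoff), stratified diagnostic test performance with confidence
    intervals, NPV-constrained cutoff search over observed D-dimer values, net
    reclassification improvement and avoided-CT-angiography cost comparison
    between rule-out strategies, a log-linear synthetic cohort generator for
    method validation, and a command-line pipeline producing report tables
    from delimited patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
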
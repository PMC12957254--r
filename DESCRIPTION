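Package: faerscreen
Title: Disproportionality Signal Screening for FAERS-Style Spontaneous Report Data
Version: 0.1.0
Authors@R:
    person("FAERS", "Screen Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for comparative pharmacovigilance on FDA
    Adverse Event Reporting System (FAERS) quarterly ASCII extracts:
    ingestion of the seven "$"-delimited tables, case deduplication and
    drug-name standardization, 2x2 contingency construction against a
    full-database background, reporting odds ratio (ROR), proportional
    reporting ratio (PRR) with Pearson chi-square, and Bayesian confidence
    propagation neural network information component (BCPNN IC) signal
    statistics with configurable criteria, system-organ-class profiling,
    age-stratified screening with multiplicity adjustment, and
    time-to-onset modelling (Weibull shape-parameter analysis,
    Kaplan-Meier cumulative incidence, log-rank and Cox two-group
    comparison). Includes a synthetic FAERS-dialect data generator with
    known ground truth so every stage is testable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    survival,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
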
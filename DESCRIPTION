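Package: triplerx
Title: Dose-Specific Screening of Adverse Three-Drug Combinations in
    Matched Case-Control Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: High-throughput screening of three-drug combinations for
    dose-specific adverse drug event (ADE) risk in claims-style data.
    Builds matched 1:1 case-control cohorts from person, diagnosis and
    pharmacy-claim tables; codes 30-day pre-index average daily dose into
    ternary exposure levels against case-median thresholds; fits a
    seven-term dose-interaction conditional logistic regression per drug
    triplet; runs an eight-test one-sided Wald battery with pooled
    Benjamini-Hochberg false-discovery-rate control to select adverse
    combination signals; and profiles odds ratios over the full dose grid
    with dose-reduction and discontinuation contrasts. Includes a seeded
    synthetic claims generator for end-to-end testing and calibration
    studies.
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
    knitr,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
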
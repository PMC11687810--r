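Package: plasmiR
Title: Plasma MicroRNA RT-qPCR Biomarker Pipeline for Diagnosis and Prognosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for circulating microRNA
    RT-qPCR panels in liquid-biopsy biomarker studies. Covers inter-plate
    calibration and quality filtering of Ct values, spectrophotometric
    hemolysis screening with per-miRNA association verdicts, model-based
    (NormFinder-style) endogenous-control selection, comparative-Ct
    normalization with fold-difference reporting, rank-based differential
    expression with false-discovery-rate control, Kaplan-Meier and log-rank
    survival analysis with maximally selected expression cutpoints,
    univariate Cox regression, and CART-style diagnostic and survival trees
    with cross-validated cost-complexity pruning. Includes a synthetic-cohort
    generator that emulates the statistical structure of multi-cohort
    case/control plasma miRNA studies for power and recovery analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    rpart,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
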
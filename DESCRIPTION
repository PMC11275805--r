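Package: metdms
Title: Deep Mutational Scanning Analysis of Kinase Inhibitor Resistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pooled-selection deep mutational scanning
    (DMS) of a kinase domain screened against ATP-competitive inhibitors.
    Simulates saturation-mutagenesis variant libraries and multinomial
    sequencing counts under growth selection, scores variant fitness on a
    cell-doubling-rate scale by wild-type-normalised log2 regression on time
    intervals, classifies inhibitor-specific resistance mutations and
    gain-/loss-of-function effects from DMSO-recentered scores, aggregates
    resistance hotspots by inhibitor type, and fits a feature-augmented,
    monotonicity-constrained gradient-boosted predictor of inhibitor fitness
    with position- and residue-partitioned cross-validation and exhaustive
    feature-subset search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
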
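Package: condorcetfusion
Title: Condorcet and Borda Count Similarity Fusion for Ligand-Based Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Similarity searching of molecular count-fingerprint databases with
    eleven association and distance coefficients, and election of a per-activity-class
    "winner" coefficient by Borda count with Condorcet pairwise comparison. Provides
    the full ligand-based virtual-screening workflow: single-reference searches,
    voting-profile construction from the top-n retrieved structures, winner election,
    re-search with the elected coefficient, and evaluation with recall at a percentage
    cutoff, enrichment factor, BEDROC, ROC AUC, Kendall's coefficient of concordance
    with tie correction, and Friedman's test. A seeded synthetic-fingerprint generator
    produces activity classes of controllable size and structural diversity embedded
    in an inactive background, so every stage is testable without commercial datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
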
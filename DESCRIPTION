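Package: dynaprot
Title: Dynamic Proteomics with Partial 15N Metabolic Labeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of dynamic (turnover) proteomics experiments that use
    partial 15N metabolic labeling (mSILAC) together with two-dimensional gel
    electrophoresis and MALDI-TOF mass spectrometry.  Computes peptide
    isotopomer distributions at unit-mass resolution for natural-abundance and
    15N-enriched material, models an observed peptide spectrum as a mixture of
    pre-existing and newly synthesized protein, and estimates the fraction of
    new synthesis by nonnegative least-squares regression.  Also provides 2-DE
    spot-table processing (gel normalization, fold-change/t-test differential
    filtering, dose-response classification), temporal expression-shape
    classification and K-means clustering with correlation distance, a
    synthetic-data generator for end-to-end validation, and pipeline drivers
    for dose-response, time-course and turnover experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
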
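Package: infantfc
Title: Infant Visual-Cortex EEG Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for midline-to-lateral functional connectivity in
    the infant visual cortex from cleaned multichannel EEG. Computes debiased
    weighted phase-lag index (dbWPLI) spectral connectivity from 1-second
    Hann-tapered overlapping epochs, aggregates it over seed-anchored occipital
    areas of interest into 6-point topographies, vector-normalizes and flips the
    topographic patterns, and derives Near- and Far-Connectivity modelling
    variables per frequency band and stimulus condition. Provides permutation
    tests of topographic group and stimulus differences, Kruskal-Wallis and
    Wilcoxon asymmetry tests with FDR correction, exhaustive-subset
    cross-validated variable selection, and ordinary least squares association,
    moderation, variance-partition and likelihood-ratio analyses. A synthetic
    cohort generator with planted band- and condition-specific phase coupling
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lmtest
Config/testthat/edition: 3
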
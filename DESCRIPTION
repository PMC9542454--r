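Package: faceemg
Title: Facial Surface EMG Affect Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for group-level analysis of facial surface
    electromyography (sEMG) recorded during affective stimulation. Provides
    muscle-specific zero-phase band-limiting and powerline-harmonic
    suppression by spectrum interpolation, RMS/MAV amplitude envelopes with
    winsorized per-subject min-max normalization, mapping of envelopes onto a
    video schedule and self-reported valence/arousal ratings, and the
    nonparametric group statistics used in this field (Friedman omnibus
    tests, paired Wilcoxon signed-rank tests with Bonferroni correction and
    star annotations, segmented Pearson correlations, and a quadratic
    valence-trend fit). A synthetic cohort generator with a configurable
    muscle-by-category effect profile makes every stage testable without
    access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
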
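Package: circanuc
Title: Circadian Analysis of Urinary Nucleoside Excretion and Rest-Activity Rhythms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying circadian rhythms in cancer patients from
    wrist actigraphy and timed urinary modified-nucleoside excretion. Fits a
    three-state hidden Markov model (inactive, moderately active, highly
    active) to minute-level activity counts and derives rest-activity indices
    (dichotomy index I<O, 24-h autocorrelation r24, rest duration, Rhythm
    Index, dominant period); fits multiple-component (12 h + 24 h) cosinor
    models to log-transformed timed excretion data with amplitude t-tests for
    rhythm detection; verifies Spearman correlations between rhythm and
    rest-activity parameters with a residual-resampling bootstrap; classifies
    post-chemotherapy excretion trends and tests their association with plasma
    CEA changes by the Freeman-Halton exact test. Includes synthetic-cohort
    generators with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
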
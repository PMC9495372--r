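Package: emgcomplexity
Title: Complexity Analysis of Surface Electromyography Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linear and nonlinear analysis of surface
    electromyography (EMG) recorded during isometric contractions.
    Implements zero-phase band-pass preprocessing, sliding root-mean-square
    amplitude, sample entropy, recurrence quantification analysis
    (percent recurrence and percent determinism) and detrended fluctuation
    analysis, together with the two-way repeated-measures statistical layer
    (Greenhouse-Geisser correction, Bonferroni post hocs, partial eta
    squared, Cohen's d) used to compare conditions and time points within
    subjects.  A synthetic-data module generates colored noise with known
    scaling exponents, surrogate EMG trials and whole simulated cohorts
    with injected effects, so every stage of the pipeline can be verified
    against known ground truth.
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
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
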
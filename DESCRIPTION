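Package: asyncbci
Title: Asynchronous Control-State Detection for P300 Spellers via
    Multiscale Sample Entropy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects whether the user of a P300 row-column speller is
    attending the oddball stimuli ("control") or ignoring them
    ("non-control") from the regularity of the ongoing EEG.  Provides
    sample entropy with Chebyshev template matching, multiscale entropy
    profiles built on anti-aliased FIR decimation with the Richman-Moorman
    reliability criterion, band-pass/common-average-reference
    preprocessing with cumulative trial extraction for the row-column
    paradigm, leave-one-out linear-discriminant classification with a
    (m, r, tau) hyperparameter grid search, channel-wise Wilcoxon tests
    with Benjamini-Hochberg correction, a synthetic oddball session
    generator with a controllable control/non-control irregularity gap,
    a plain-text session container, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    jsonlite,
    data.table,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
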
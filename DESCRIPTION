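Package: ethosyntax
Title: Markov Syntax Analysis of Behavioral Ethograms
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analyzing the syntax of behavioral sequences recorded as
    frame-level ethograms, developed around Drosophila melanogaster grooming.
    Discretizes label streams into bouts, bins bout durations into per-action
    equal-occupancy categories, estimates maximum-likelihood first-order Markov
    transition matrices over action-by-duration state spaces, constructs
    analytic and Monte-Carlo permutation null models (duration-permuted and
    order-permuted), compares models by BIC, quantifies grooming motifs and the
    long-time anterior-to-posterior progression, and simulates synthetic
    ethograms from a nonstationary Markov renewal process with a linearly
    interpolated transition matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
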
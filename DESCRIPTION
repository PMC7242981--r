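Package: vocospan
Title: Noise-Band Vocoding and Serial-Recall Individual-Differences Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how short-term memory predicts recognition of
    spectrally degraded speech. Implements noise-band channel vocoding with
    Greenwood-spaced rectangular analysis bands, constrained digit- and
    word-span list generation, position-wise serial-recall and key-word
    scoring, and the associated individual-differences statistics:
    principal-component composite scores with the eigenvalue retention rule,
    correlation tables with Bonferroni families, standard major axis
    regression, iterative upper-tail reaction-time trimming, geometric-mean
    condition costs, tie-corrected Wilcoxon signed-rank tests, and
    maximum-likelihood ex-Gaussian reaction-time fits. A calibrated synthetic
    cohort generator produces complete sessions with known latent structure so
    the full pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
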
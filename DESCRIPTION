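Package: mmnlearn
Title: Trial-by-Trial Modelling of Mismatch Negativity Amplitudes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates roving-oddball tone sequences and synthetic single-trial
    EEG data, extracts trial-wise mismatch negativity (MMN) amplitudes from
    epoched waveforms, and compares thirteen competing models of how those
    amplitudes evolve over trials: change-detection and neural-adaptation
    models, and nine readouts of a free-energy Bayesian observer that learns
    tone categories, expected train length and transition structure online.
    Model evidence is computed per subject under a conjugate Bayesian linear
    regression (closed form and Monte-Carlo), and models and model families
    are compared with random-effects Bayesian model selection, including
    exceedance probabilities and family-level inference over predefined
    partitions of the model space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
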
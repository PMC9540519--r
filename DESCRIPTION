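Package: affectbci
Title: Affective fNIRS Brain-Computer Interface Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating a two-class affective
    brain-computer interface from multichannel prefrontal functional
    near-infrared spectroscopy (fNIRS) recordings. Implements the full
    closed-loop pipeline: synthetic session generation with a double-gamma
    hemodynamic response and band-limited physiological noise, causal
    Chebyshev type II low-pass filtering with block-baseline correction,
    seven temporal trial features, sequential floating forward channel
    selection under the Fisher criterion, shrinkage-regularized linear
    discriminant classification with posterior probabilities, block-wise
    adaptive retraining with cumulative online prediction and neurofeedback
    values, and chance-calibrated evaluation via exact binomial thresholds
    and repeated stratified cross-validation with in-fold selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
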
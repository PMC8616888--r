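Package: innuq
Title: Interval Neural Networks for Uncertainty Quantification in Signal
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-hoc, deterministic uncertainty quantification for trained
    feed-forward reconstruction networks via interval arithmetic. Wraps the
    weights and biases of a trained ReLU network in intervals, propagates
    inputs with sound interval arithmetic, and trains the interval bounds
    with a hinge-plus-width loss so that the resulting prediction intervals
    are guaranteed to contain the original prediction and carry directional
    uncertainty information. Includes the Monte Carlo dropout and direct
    variance estimation (mean/variance head) baselines, a synthetic
    one-dimensional deconvolution benchmark built on a discrete cosine
    transform forward operator, box-constrained adversarial perturbation of
    inputs, and evaluation protocols for prediction-error, adversarial, and
    atypical-artifact failure-mode detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
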
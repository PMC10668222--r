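Package: triloc
Title: Trilateration Models of Tactile Localization on Hand-Held Tools
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Probabilistic models of how touch is localized on a hand-held
    rod. Implements a Bayesian trilateration observer with
    distance-dependent noise and maximum-likelihood cue fusion, the
    vibratory feature space of a cantilever rod (mode shapes and
    location-to-motif mapping), a three-layer probabilistic
    population-coding network with Poisson spiking that converts mode
    amplitudes into a tool-centered location estimate, a boundary
    truncation alternative model, and a model-comparison pipeline (variable
    errors, nonlinear least-squares fitting, BIC) together with a synthetic
    behavioral-data generator so the full analysis runs end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
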
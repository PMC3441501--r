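Package: ellshape
Title: Correlation Shaping in the Electrosensory ELL-EGp Feedback Circuit
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and linear-response analysis of the open-loop
    feedback circuit formed by deep electrosensory lateral line lobe (ELL)
    pyramidal neurons, granule cells of the posterior eminentia granularis
    (EGp), and superficial ELL pyramidal neurons in weakly electric fish.
    Provides a three-population leaky integrate-and-fire network simulator,
    estimators for spike-train and spike-count correlation statistics
    (covariance functions, windowed count correlations, within- and
    across-trial variants, cross-spectra and stimulus gain), a
    Fokker-Planck threshold-integration implementation of the
    single-neuron susceptibility and power spectrum, closed-form
    predictions for stimulus gain and spike-count correlation versus
    counting-window size, and a signal-versus-distractor signal-to-noise
    analysis of the population code. Synthetic spike-train generators with
    known closed-form statistics are included so every estimator can be
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    pracma,
    signal,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
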
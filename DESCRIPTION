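Package: ingnet
Title: Simulation and Analysis of High-Frequency Oscillations in
    Inhibitory Interneuron Networks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates all-to-all inhibitory networks of integrate-and-fire
    (IF) and generalized integrate-and-fire (GIF) neurons on a two-dimensional
    torus with distance-dependent conduction delays, conductance-based
    synapses, and rectified Ornstein-Uhlenbeck background conductances, in
    the fluctuation-driven regime where single cells fire irregularly but the
    population oscillates at ~100 Hz (interneuron network gamma). Provides
    closed-form linear analysis of the subthreshold dynamics (resting
    potential, eigenvalues, effective time constant and intrinsic frequency),
    firing-rate threshold calibration, and a measurement suite: single-cell
    spiking statistics, Mean Phase Coherence, population-rate spectra with
    Gaussian-fit peak frequency, windowed sinusoidal phase analysis of
    mean-field traces, circular-linear correlation, and phase-conditioned
    kernel density estimates of membrane currents.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
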
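Package: decolle
Title: Online Local Learning for Deep Spiking Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and training of deep spiking neural networks with
    deep continuous local learning (DECOLLE): discrete-time leaky
    integrate-and-fire neurons with synaptic traces and a relative
    refractory mechanism, fixed random local readouts with per-layer
    losses, a boxcar surrogate-gradient three-factor plasticity rule with
    optional sign-concordant error feedback, firing-rate regularizers and
    the AdaMax optimizer. Weight updates are made online at every
    simulation time step and require no storage of activation history, so
    the memory cost of training is independent of sequence length.
    Includes generators for Poisson spike trains, time-varying regression
    pseudo-targets and dynamic-vision-sensor-like polarity event streams,
    together with the event binning, spatial downsampling and slicing
    preprocessing used for event-based vision, and a small command-line
    driver for running regression and gesture-like classification
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
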
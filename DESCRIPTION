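Package: striatnet
Title: Striatal Medium Spiny Neuron Network Simulation and Spike-Train Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates recurrent inhibitory networks of conductance-driven
    medium spiny neurons (MSNs) parameterized by feedforward excitation and
    recurrent collateral inhibition, computes a fifteen-statistic battery of
    inter-spike-interval (ISI) features from single-unit spike trains, and
    estimates the two network parameters from spiking data by Kullback-Leibler
    matching of median-split joint feature distributions against a library of
    model simulations. Includes population-level diagnostics (rate-correlation
    eigenvalue entropy, K-means raster ordering), Markov-modulated Poisson
    surrogate generators for burst-firing phenotypes, dataset segmentation and
    age-interval construction utilities, and an end-to-end parameter-recovery
    validation of the estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
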
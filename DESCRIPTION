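Package: lplearn
Title: Latent Predictive Learning Plasticity for Rate and Spiking Networks
Version: 0.1.0
Authors@R:
    person("LPL", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for latent predictive learning (LPL), a local
    synaptic plasticity rule that combines a temporal-prediction error with
    variance-modulated Hebbian metaplasticity and a decorrelation term.
    Provides the rate-based rule with closed-form weight updates and classic
    baselines (Oja, Hebbian-only, predictive-only), layer-local training of
    small multi-layer networks, a fixed-step conductance-based
    leaky-integrate-and-fire network simulator with the spiking form of the
    rule and inhibitory spike-timing-dependent plasticity, spike-pairing
    induction protocols, synthetic input generators (two-cluster 2D
    sequences, slow Fourier rate signals with shuffled controls,
    inhomogeneous Poisson rasters, latent-factor glyph videos), and
    representation metrics (selectivity, participation ratio, linear
    readout, signal reconstruction, representational similarity,
    disentanglement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
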
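Package: csbp
Title: Chaotic Spiking Backpropagation for Spiking Neural Networks
Version: 0.1.0
Authors@R:
    person("Ziqian", "Holt", email = "zholt@example.org", role = c("aut", "cre"))
Description: Training of leaky integrate-and-fire spiking neural networks by
    surrogate-gradient backpropagation through time, augmented with a
    neuron-intrinsic chaotic loss whose intensity is annealed geometrically
    (chaotic simulated annealing). Includes a dynamical-systems analysis
    suite for the resulting weight-update map: maximum Lyapunov exponent
    estimation by the two-trajectory Benettin method, bifurcation scans over
    the chaos intensity, numerical fixed-point location with Jacobian
    spectra, and snap-back repeller verification. Ships desk-scale task
    fixtures (XOR spike encoding, a sine regression set), experiment
    drivers, a JSON run-configuration format and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
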
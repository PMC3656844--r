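Package: sfmnet
Title: Structured Flows on Manifolds from Spiking Theta-Neuron Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates networks of theta (Ermentrout-Kopell style) spiking
    neurons with pulse-coupled synaptic drive, reduces them to firing-rate
    and spike-timing (phase) descriptions, and analyses how breaking the
    symmetry of the coupling matrix sculpts low-dimensional flows: fixed
    points, limit cycles, bistability and monostable (excitable) dynamics.
    Includes mean-field mode analysis, nullcline and polynomial-nullcline
    tools, phase-response curves with closed-form and simulated variants,
    Kuramoto order-parameter and synchronous-mode stability analysis,
    two-neuron phase-locking maps, a three-node heteroclinic family with a
    singular-vector phase reduction and bifurcation scans, and composition
    of multifunctional circuits whose flow transitions are detected by a
    sliding-window principal-component subspace-similarity statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    deSolve,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
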
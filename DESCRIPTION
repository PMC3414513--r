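Package: hourglass
Title: Phase-Plane Analysis of Calcium-Shaped Neuronal Excitability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and dynamical-systems analysis of conductance-based
    neuron models in which slowly activating calcium currents reshape the
    classical FitzHugh-Nagumo phase portrait. Provides the Hodgkin-Huxley
    model, its calcium-augmented variant, and a thalamocortical relay neuron
    model; two-variable planar reductions; nullcline, equilibrium, saddle
    manifold and transcritical-singularity computation; one-parameter
    bifurcation diagrams (fold, Hopf, homoclinic, saddle-node of limit
    cycles); transcritical and fold hybrid (integrate-and-reset) models with
    slow adaptation; and detectors for the triple electrophysiological
    signature of high calcium conductance (spike latency, plateau
    oscillations, afterdepolarization).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
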
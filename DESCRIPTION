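Package: respcpg
Title: Reduced Respiratory Central Pattern Generator Model and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and dynamical-systems analysis of a reduced
    respiratory central pattern generator network: coupled non-spiking
    pre-I, early-I, post-I, aug-E (and optionally PiCo) units with
    persistent-sodium slow inactivation, mutual synaptic inhibition and
    tonic excitatory drives. Provides the model equations with a
    compiled right-hand side, attractor-finding integration,
    three-phase rhythm metrics (period, inspiratory and expiratory
    phase durations, amplitude), isolated-unit fixed-point and Hopf
    bifurcation analysis with a two-parameter oscillatory/tonic
    transition curve, phase-plane geometry (nullclines, curves of left
    knees and fixed points, escape events), and parameter-sweep
    experiments that probe masking of intrinsic pacemaker dynamics by
    network interactions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
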
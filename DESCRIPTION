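Package: pdresonance
Title: Subthreshold Resonance Analysis of Pyloric Dilator Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Conductance-based (Hodgkin-Huxley-type) model of the crustacean
    pyloric dilator (PD) neuron with transient and persistent calcium currents,
    a hyperpolarization-activated inward current, a calcium-dependent potassium
    current and first-order intracellular calcium buffering.  Provides quasi-active
    linearization of the model around a holding potential into an equivalent
    electrical RLC circuit (including the five calcium-feedback branches of the
    KCa channel), chirp (ZAP) stimulus generation, FFT-based impedance profiling
    with local-regression smoothing, resonance metrics (resonance frequency,
    peak impedance, Q-factor), and experiment drivers for channel knockouts,
    holding-potential sweeps, conductance sweeps and circuit-component tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
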
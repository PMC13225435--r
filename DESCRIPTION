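Package: rgcmg
Title: Magnesium Neuroprotection in a Conductance-Based Retinal Ganglion Cell Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Single-compartment Hodgkin-Huxley-type model of a retinal
    ganglion cell with AMPA and NMDA receptor synaptic input, voltage-dependent
    magnesium block of NMDA receptors in the Jahr-Stevens form, and single-pool
    intracellular calcium dynamics. Provides fixed-step forward-Euler and
    Runge-Kutta integrators with convergence diagnostics, glutamate pulse-train
    stimulation protocols, dose-response sweeps over stimulation frequency and
    extracellular magnesium with therapeutic-window classification under dual
    neuroprotection and function-preservation criteria, and intervention-timing
    analysis with protection-efficacy and calcium-progress metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
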
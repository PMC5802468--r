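Package: pleiosim
Title: Pleiotropic Ion-Channel Variant Effects on Neuronal Firing and
    Cardiac Pacemaking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based models of a reduced layer-V pyramidal
    neuron and of mouse-type and rabbit-type sinoatrial node pacemaker
    cells, together with a framework for applying ion-channel and
    calcium-transporter variant effects to model parameters, downscaling
    those effects until behaviour-preservation conditions are marginally
    satisfied, running excitability protocols (f-I curves, rheobase
    search, pacemaking-rate measurement), simulating one-dimensional
    cell chains and two-dimensional monodomain sinoatrial/atrial tissue,
    and aggregating per-variant outcomes into cross-cell-type
    correlation and pleiotropy-classification analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
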
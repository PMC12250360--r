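Package: oicsim
Title: Simulation of Coupled Serotonin and Opioid Signalling in the
    Enteric Nervous System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic mass-action modelling of the serotonergic and
    mu-opioid signalling pathways that converge on adenylyl cyclase in
    enteric neurons.  Builds the 25-reaction network coupling serotonin
    release, receptor binding, G-protein cycling, adenylyl cyclase
    activation/inhibition and cyclic AMP turnover; integrates it with
    LSODA; generates agonist and inhibition dose-response curves with
    four-parameter logistic (Hill) fits yielding EC50, IC50 and pIC50;
    calibrates the cyclic AMP production law from steady-state
    dose-response data (including a synthetic-data generator for the
    calibration stage); and runs acute opioid treatment experiments
    reporting cyclic AMP recovery times, drug depletion times, receptor
    occupancy, and degradation-rate sweeps.  Networks can be exported to
    and re-imported from SBML Level 3.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    xml2,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
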
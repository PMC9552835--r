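Package: cabgflow
Title: Pulsatile 1D-0D Haemodynamics of Coronary Circulations with Stenoses and Bypass Grafts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pulsatile blood flow and pressure in arterial networks of
    one-dimensional elastic vessel segments coupled to lumped-parameter
    (three-element Windkessel) outlets, aimed at coronary circulations before and
    after bypass grafting. Provides network topology editing (side-branch taper,
    lumped stenoses, in-situ, free-aortic, Y-composite, sequential and extension
    grafts), a Richtmyer two-step Lax-Wendroff solver with Newton-Raphson junction
    coupling, automatic calibration of outlet resistances and compliances from
    flow prescriptions, and the surgeon-facing transit-time-flowmetry metrics
    (mean graft flow, pulsatility index, backflow and diastolic filling
    percentages) together with the instantaneous wave-free ratio and regional
    myocardial perfusion.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
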
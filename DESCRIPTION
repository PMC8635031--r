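Package: trnreduce
Title: Reduced-Model Dynamics of Thalamic Reticular Nucleus Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a six-variable conductance-based model of thalamic
    reticular nucleus (TRN) neurons (fast sodium, delayed-rectifier
    potassium, low-threshold T-type calcium and two leak currents), reduces
    it to a three-variable model by converting gating variables to
    equivalent potentials and grouping them by time scale with optimal
    state-dependent weights, and provides a fast-slow bifurcation toolkit:
    current-voltage relations, equilibrium location and linear stability,
    limit-cycle probes, fold, saddle-homoclinic, fold-cycle and
    Andronov-Hopf bifurcation detection, spike and burst statistics, and
    one-parameter bifurcation diagrams in the injected current.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    tools,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
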
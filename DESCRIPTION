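Package: neocalib
Title: Two-Phase Recalibration of Stochastic Colorectal Neoplasia
    Microsimulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Individual-based state-transition engines for colorectal
    neoplasia natural history (a discrete-time cycle engine and a
    discrete-event dwell-time engine with Johnson SB dwell durations),
    together with a two-phase procedure for recalibrating such expensive
    stochastic simulators against prevalence targets: a global sampling
    phase (Latin hypercube screening, progressive grid and orthogonal
    sampling over parameter pairs) followed by a budget-constrained
    Nelder-Mead simplex phase, run either over the full parameter space
    or sequentially over ordered parameter blocks.  Includes prevalence
    extraction from simulation traces, a weighted sum-squared
    relative-error calibration loss, synthetic-target generation for
    parameter-recovery studies, and a benchmark harness comparing
    calibration strategies under fixed evaluation budgets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lhs,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
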
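Package: zabedopk
Title: Phase-1 Pharmacokinetic and Target-Occupancy Analysis for an Oral IRAK4 Inhibitor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Noncompartmental and model-based analysis of phase-1 trials of the
    oral IRAK4 inhibitor zabedosertib. Provides a NONMEM-style trial-data model
    with BLQ handling, a seeded generator of single-ascending-dose,
    multiple-ascending-dose and food-effect/absolute-bioavailability study
    datasets, a noncompartmental analysis engine (terminal-slope estimation,
    linear-up/log-down AUC, multiple-dose accumulation metrics), exposure
    statistics (geometric mean ratios with 90 percent confidence intervals,
    dose-proportionality power models, crossover food-effect ANOVA, absolute
    bioavailability against an intravenous microtracer), a one-compartment
    structural model with dose-dependent bioavailability and capacity-limited
    kinetic plasma protein binding, a two-stage population fitter, and a
    kinetic IRAK4 target-occupancy projector driven by unbound exposure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    ggplot2
Config/testthat/edition: 3
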
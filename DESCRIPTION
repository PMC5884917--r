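Package: precstep
Title: Simulation and Analysis of Treadmill Precision Stepping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying precision stepping on an instrumented
    treadmill with belt-fixed projected step targets. Generates stepping
    protocols (unperturbed blocks and blocks with unexpected forward or
    backward target shifts at graded available response distances),
    simulates cohorts of walkers with ground-truth marker and
    center-of-pressure signals, detects foot-strike and toe-off events from
    the center-of-pressure butterfly, scores signed anteroposterior step
    errors at midstance, and runs the cohort-level statistics: Pearson and
    partial correlations, repeated-measures ANCOVA with Greenhouse-Geisser
    correction, Benjamini-Hochberg false discovery rate control, and
    permutation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
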
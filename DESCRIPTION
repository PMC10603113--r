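Package: redoxlan
Title: Kinetic Modelling of Iron Redox Communication in Microbial Co-Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the Fe3+/Fe2+ redox signal exchanged in a
    two-species "biological LAN": an iron-reducing signal router
    (Shewanella putrefaciens) and an iron-oxidizing bio-actuator
    (Rhodopseudomonas palustris) coupled through a shared iron pool, read
    out by a persistent-luminescence nanoprobe. Provides log-linear
    luminescence and absorbance calibration with inverse prediction,
    four-parameter logistic transduction kinetics for monocultures, a
    coupled ordinary-differential-equation co-culture model with an iron
    redox-cycle term, nonlinear least-squares parameter estimation from
    multi-channel time courses, a parameter-recovery harness, and a
    synthetic time-series generator so that every stage can be exercised
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
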
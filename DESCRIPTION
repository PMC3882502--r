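Package: mamscreen
Title: Optimal Multi-Arm Screening Trial Design for Drug Development
    Programs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Planning tools for multi-arm screening trials embedded in a
    drug-development program. Computes, analytically or by simulation, the
    expected number of patients recruited until the first confirmed
    treatment (ESS) when candidate treatments are screened in multi-arm
    phase II trials and promising ones are tested in confirmatory phase
    III trials.  Supports four design families: top-treatment and
    all-interesting-treatments progression rules, each with single-stage
    or group-sequential (triangular-boundary) confirmatory trials,
    including multi-arm confirmatory trials with Dunnett-type family-wise
    error control.  Optimizes the screening design (number of arms, per-arm
    sample size, progression threshold) to minimize ESS via Nelder-Mead
    search with integer refinement, and provides a simulation engine with
    common random numbers for design families without analytic formulae.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    statmod,
    stats,
    utils,
    yaml
Suggests:
    mvtnorm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
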
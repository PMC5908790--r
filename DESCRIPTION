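Package: panelscreen
Title: Growth-Based Drug Screen Analysis: Dose-Response Metrics, Combination
    Synergy, Biomarker Association and Xenograft Efficacy
Version: 0.2.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for time-zero-anchored cell-line proliferation
    screens and their follow-on studies. Normalizes raw viability plate signals
    to a T0 anchor, fits four-parameter logistic concentration-response curves
    and extracts growth metrics (gIC50, gIC100, dEC50, Ymin-T0) with explicit
    censoring; scores fixed-ratio drug combinations with mutually non-exclusive
    Chou-Talalay combination indices and a three-tier CI/fold-shift synergy
    classification; associates mutation status with potency via rank-sum and
    exact 2x2 enrichment tests at gene and residue level; and analyzes
    xenograft efficacy via time-to-endpoint, percent tumor growth delay,
    log-rank tests and day-fixed tumor growth inhibition. Includes a synthetic
    screen generator (Loewe-additive fixed-ratio mixtures with a controllable
    synergy parameter, mutation-linked potency multipliers, exponential tumor
    growth) so the whole pipeline is testable against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
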
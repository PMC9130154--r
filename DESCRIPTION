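Package: ceatree
Title: Decision-Tree Cost-Effectiveness Analysis of Diagnostic Imaging
    Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A decision-analytic engine for one-period cost-effectiveness
    models of diagnostic strategies, built around an expected-value rollback
    of a typed decision tree (decision, chance and terminal nodes whose
    probabilities and payoffs are auditable expressions over named
    parameters). Computes quality-adjusted life years (QALYs), incremental
    cost-effectiveness ratios (ICER), net monetary benefit (NMB), dominance
    and the efficiency frontier; deterministic one-way, tornado and
    threshold sensitivity analyses; and Monte-Carlo probabilistic
    sensitivity analysis with moment-matched beta and gamma distributions,
    cost-effectiveness acceptability curves and incremental scatter output.
    Ships a ready-to-run model of computed-tomography triage (cone-beam CT
    versus multi-slice CT after conventional radiography) for complex
    phalangeal fractures, plus a patient-level microsimulation that serves
    as an independent check on the cohort rollback.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
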
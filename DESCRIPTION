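Package: asthmaCUA
Title: Cost-Utility Markov Model for Biomarker-Guided Pediatric Asthma Management
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Three-state Markov cohort model (well-controlled, sub-optimal
    control, exacerbation) with weekly cycles for comparing sputum-eosinophil-
    guided, FeNO-guided and standard management of persistent childhood asthma
    from a societal perspective. Provides deterministic base-case evaluation,
    incremental cost-effectiveness ratios, net monetary benefit, dominance and
    the efficiency frontier; one-way deterministic sensitivity analysis;
    second-order Monte Carlo probabilistic sensitivity analysis with
    cost-effectiveness-plane and acceptability-curve outputs; moment-matched
    beta, gamma, lognormal and Dirichlet parameter priors; calibration of
    unreported state costs and testing schedules to published arm-level
    results; and a patient-level microsimulator used to cross-validate the
    cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
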
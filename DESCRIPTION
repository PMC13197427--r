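Package: personarouter
Title: Persona Routing and Metamorphic Safety Evaluation for Structured Clinical Plans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline evaluation pipeline for persona-prompted clinical
    decision support outputs. Validates structured clinical-plan JSON and
    JSONL run logs, scores each plan with rule-based metrics (test counts,
    diagnostic-breadth entropy, ordinal disposition acuity, discharge
    safety-net specificity, contraindication and sequence trap severity),
    routes among stored persona outputs with red-flag-triggered escalation
    strategies and simulated-call accounting, checks counterfactual
    monotonicity of Base/Worse vignette pairs (a metamorphic safety
    property), and summarizes violation rates with Wilson score confidence
    intervals. A seeded synthetic persona-output generator replaces the
    language model so the whole pipeline runs deterministically offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    stats,
    stringi,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
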
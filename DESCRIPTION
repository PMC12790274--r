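Package: osteoscreen
Title: Cost-Effectiveness Microsimulation of AI-Based Opportunistic
    Osteoporosis Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Health-economic evaluation of opportunistic osteoporosis
    screening on routine chest radiographs with an AI classifier, for the
    South Korean population aged 50 and over.  A decision-tree screening
    cascade (AI flag, DXA confirmation, treatment initiation) feeds an
    individual-level Markov microsimulation of hip, vertebral and non-hip
    non-vertebral fractures with annual cycles, treatment persistence and
    effect waning, post-fracture excess mortality and nursing-home costs.
    Reports discounted costs, QALYs, life-years and incremental
    cost-effectiveness ratios, with deterministic one-way sensitivity
    analyses, probabilistic sensitivity analysis and cost-effectiveness
    acceptability curves.  Unpublished inputs (life tables, population
    structure, post-fracture mortality, subsequent-fracture risk) are
    provided as clearly flagged synthetic stand-ins.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
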
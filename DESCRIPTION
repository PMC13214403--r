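Package: achecon
Title: Cost-Effectiveness and Budget Impact of Limb Lengthening in
    Achondroplasia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discrete-time Markov cohort model comparing two-stage surgical
    limb lengthening with no treatment in achondroplasia. Provides annual
    life-table handling with a Gompertz-Makeham synthetic generator and the
    10-year life-expectancy reduction used for achondroplasia, cycle-indexed
    transition matrices for both strategies, cohort propagation, discounted
    QALY and cost valuation (ICER, net monetary benefit), probabilistic
    sensitivity analysis with beta and gamma parameter distributions,
    cost-effectiveness acceptability curves and frontier, expected value of
    perfect information, and a multi-cohort budget impact model, plus a
    configuration-file driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
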
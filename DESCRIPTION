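Package: gencea
Title: Cost-Effectiveness Analysis of Genetic and Genomic Testing Strategies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Decision-tree cost-effectiveness modelling for sequential
    genetic and genomic testing strategies in rare disease diagnosis.
    Evaluates each strategy's expected discounted cost and diagnostic
    yield over a multi-year horizon, performs incremental analysis
    (incremental cost per additional diagnosis, strict and extended
    dominance, efficiency frontier), net-monetary-benefit threshold
    (one-way) sensitivity analysis, and probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves. Ships a
    model of six testing strategies for rare developmental
    disorders as its canonical configuration, plus a generator of
    structurally faithful synthetic model configurations for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
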
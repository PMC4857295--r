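Package: nntdesign
Title: Planning Biomarker Validation Studies on the Number-Needed-to-Treat Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning clinically meaningful validation studies of
    binary biomarker tests. An elicited number-needed-to-treat (NNT)
    "discomfort range" is converted into required positive and negative
    predictive values; a closed-form inversion of Bayes theorem
    ("contra-Bayes") converts those predictive values, at a stated
    prevalence, into the sensitivity and specificity a retrospective
    case-control study must demonstrate. Prospective and retrospective
    design summaries provide exact (Clopper-Pearson) confidence intervals
    on the predictive-value and NNT scales, and Monte-Carlo predictive
    intervals for NNT under independent Jeffreys posteriors. A feasible
    region of predictive-value pairs can be computed on a grid and exported
    for plotting, and a step-by-step study-design scaffold can be run from
    a YAML or JSON configuration file or from the bundled command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
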
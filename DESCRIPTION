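Package: mdsrpi
Title: Performance Evaluation of Maternal Death Surveillance and Response Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate the implementation of Maternal Death
    Surveillance and Response (MDSR) systems. Computes health-facility
    readiness scores across four surveillance dimensions (structure, core,
    supportive, attributes) with Ethiopian Public Health Institute (EPHI)
    functionality ratings; the five-indicator MDSR Performance Index
    (MDSRPI) with its weighted composite and low/moderate/good performance
    classes; group comparisons (t-tests, one-way ANOVA with Bonferroni
    post-hoc contrasts, summary-statistic approximations); Mann-Kendall
    trend tests with Sen's slope and confidence intervals; multi-stage
    survey-design arithmetic (design effect, finite-population-corrected
    stratum sizes, probability-proportional-to-size allocation); and a
    synthetic survey generator for parameter-recovery testing. Ships the
    published Ethiopian 2014-2020 regional count panel as a fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
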
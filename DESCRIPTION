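Package: prscreen
Title: Screening-Performance Calculus for Polygenic Risk Scores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for appraising the screening performance of polygenic
    risk scores under the equal-variance Gaussian (binormal) model.
    Converts commonly reported performance measures (odds ratio per
    standard deviation, extreme-quantile odds ratios, area under the ROC
    curve) to and from the mean separation between affected and
    unaffected score distributions, and derives detection rates, false
    positive rates, likelihood-ratio risk profiles, positive predictive
    values, risk-stratification tables and number-needed-to-genotype
    arithmetic. Includes a seedable synthetic-cohort simulator for
    Monte-Carlo validation of every closed form, a reader for tables of
    published metrics, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
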
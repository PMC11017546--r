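Package: crosslag
Title: Time-Stratified Case-Crossover Distributed-Lag Models for
    Short-Term Environmental Exposures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating short-term health effects of daily
    environmental exposures (fine particulate matter, temperature) with a
    time-stratified case-crossover design and distributed lag models.
    Classifies healthcare records into respiratory outcome categories from
    ICD-10-CM codes, selects bidirectional same-weekday referent days within
    calendar month and year, builds single-day, cumulative and weekly-average
    lagged exposure covariates, fits conditional logistic regression by
    Newton-Raphson maximisation of the exact conditional likelihood, and
    summarises effect modification by temperature percentiles or season
    through delta-method linear combinations of coefficients. Includes a
    synthetic-data generator with known ground truth so parameter recovery,
    confidence-interval coverage and type-I error of the whole pipeline can
    be verified end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
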
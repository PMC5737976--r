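Package: caritrend
Title: Trend Detection and Power Analysis for Coastal Monitoring Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying long-term change in coastal water
    temperature and visibility (Secchi distance) from station monitoring
    networks such as CARICOMP. Fits harmonic-seasonal linear-trend models
    with AR(1) noise by generalized least squares with a profiled
    autocorrelation parameter, classifies station trends, computes
    trend-detectability (years-to-detect) power estimates, constructs
    station-level covariates (fetch-based wave exposure, current speed,
    population change, rainfall trend), and models trend categories with
    multinomial logistic regression. Includes a synthetic-data generator
    that emulates weekly sampling with gaps, seasonality, linear trends,
    and AR(1) noise so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    nnet,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
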
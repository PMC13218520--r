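Package: basketproxy
Title: Behavioural Proxy Measures of Menstrual Pain from Retail Transaction Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving probabilistic proxy measures of menstruation,
    pain and menstrual pain from itemised retail transaction logs. Baskets
    containing menstrual and pain-relief products are identified and used to
    estimate conditional purchase propensities, including the Menstrual Pain
    Purchasing Ratio (MPR), the ratio of the probability that a basket
    contains a pain product given it contains a menstrual product to the same
    probability for non-menstrual baskets. The package validates the
    menstruation proxy through inter-purchase interval periodicity, aggregates
    proxies to small areas (MSOAs), links them to area deprivation features,
    classifies areas as high or low proxy prevalence under cross-validation,
    and ranks features by Shapley attribution. A calibrated synthetic
    transaction-log simulator with a ground-truth record supports parameter
    recovery experiments in place of private retailer data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    glmnet,
    ranger,
    e1071,
    nnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
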
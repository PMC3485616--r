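Package: winpct
Title: Win Percentage Analysis of Classifier Suitability
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assesses the suitability of candidate classifiers to a two-class
    dataset by "win percentage": the probability that each classifier performs
    best on a finite random sample of feature sets. Implements six Gaussian
    Bayes classifiers with constrained covariance (nearest centroid through
    quadratic discriminant analysis), cross-validated balanced accuracy, a
    Monte Carlo wrapper feature-selection algorithm with sample-size planning,
    continuous (order-statistic quadrature) and discrete (rank-weight) win
    percentage, a beta-distribution null model for significance testing, and
    synthetic-data generators for validating the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    e1071,
    withr,
    yaml,
    jsonlite,
    data.table,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
biocViews: Classification, FeatureExtraction, Microarray, StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
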
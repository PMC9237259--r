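Package: fosnet
Title: c-Fos Functional Connectivity Networks for Small-Cohort Brain Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds interregional functional-connectivity networks from
    per-animal regional c-Fos counts. Provides group-summary and cohort
    table input/output, a calibrated synthetic-cohort generator (Gaussian
    copula with truncation accounting and planted correlation structure),
    one-way ANOVA and Tukey comparisons including reconstruction from
    printed mean/SEM summaries, per-group correlation networks with
    thresholding, degree and betweenness centralities, hub identification,
    motor-subnetwork and seed-centered (ego) analyses, a five-regressor
    behavior-prediction stage with dual importance normalisations, and a
    deterministic end-to-end pipeline with a machine-readable report bundle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    xml2,
    randomForest,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
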
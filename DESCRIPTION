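Package: plastmeta
Title: Meta-Analysis of Plastic Residue Effects on Soil Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for synthesising control-versus-plastic
    comparisons of soil microbial community parameters. Computes
    observation-level log response ratios with sampling variances
    (including coefficient-of-variation imputation of missing standard
    deviations and ordination-derived beta-diversity and community-structure
    response ratios), pools them with random/mixed-effects weighting and
    between-group heterogeneity tests, fits a linear / additive-smooth /
    broken-stick model cascade to estimate dose-response thresholds,
    ranks moderators by tree-ensemble variable importance, and screens for
    publication bias. Ships a synthetic meta-dataset generator with planted
    truths so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mgcv,
    randomForest,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
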
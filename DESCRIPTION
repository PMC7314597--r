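Package: cogsom
Title: Self-Organizing Map Analysis of Cognitive Training Response Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping multivariate cognitive assessment profiles with
    batch-trained self-organizing maps (SOMs) and for quantifying how working
    memory training reshapes them. Provides a deterministic batch SOM engine
    with PCA-based linear initialization and a shrinking boxcar neighbourhood;
    leave-N-out cross-validation of map representativeness via K-nearest-node
    prediction against shuffled-prediction permutation nulls; component-plane
    representational similarity analysis with bootstrap tests for
    training-induced changes in pairwise task relationships; K-means
    subgrouping of map nodes with best-matching-unit participant allocation,
    silhouette diagnostics and bootstrap retrain stability; and pre/post
    transition analysis of improvement trajectories (mover/stayer interest
    groups, gain-score and covariate ANOVAs). A synthetic cohort simulator
    calibrated to published age-standardized working memory assessment
    summaries makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    cluster,
    jsonlite,
    mclust,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
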
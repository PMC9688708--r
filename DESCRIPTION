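Package: spaclust
Title: Unsupervised Clustering of Cerebrovascular and Systemic
    Physiological Reactivity Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies subjects into physiological-reactivity groups from
    features derived from systemic physiology augmented functional
    near-infrared spectroscopy (SPA-fNIRS) recordings of a task performed
    under colored light exposure. Provides a synthetic multichannel
    time-series cohort generator with planted group structure, task-phase
    area-under-curve feature extraction, min-max normalization and PCA
    projection at an explained-variance threshold, a constrained exhaustive
    five-feature subset search scored by silhouette, six clustering methods
    (k-means, k-medoids, hierarchical, Gaussian mixture, DBSCAN,
    self-organizing map) under a uniform hard-label contract, three cluster
    validity indices with majority-vote consensus over the optimal number of
    clusters, and a config-driven end-to-end pipeline with plain-text
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    cluster,
    mclust,
    pracma,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
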
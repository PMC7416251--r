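Package: kminit
Title: Hybrid Centroid Initialization for K-Means Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Batch K-means clustering with three hybrid centroid
    initialization strategies (minimum-spanning-tree skeleton points,
    genetic-algorithm centroid search, and hierarchical tree cuts),
    baseline clusterers (agglomerative, DBSCAN, EM Gaussian mixture),
    eleven internal and external cluster validity indices, optimal-k
    selection by a silhouette/gap/elbow majority rule, and a two-phase
    benchmarking pipeline for comparing initialization strategies on
    standardized feature tables and labelled Gaussian-mixture synthetic
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
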
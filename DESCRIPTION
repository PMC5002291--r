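Package: scarSOM
Title: Self-Organizing Map Analysis of Polyethylene Wear-Scar Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Clustering analysis of binary wear-scar images from tibial
    polyethylene inserts of total knee replacements. Provides a from-scratch
    batch and sequential self-organizing feature map (SOFM) with a linear
    neighborhood-radius schedule, u-matrix computation and automated cluster
    delineation, assignment of held-out components to an existing cluster
    structure, clustering robustness statistics (pairwise co-membership
    agreement, Cohen's kappa, intraclass correlation), geometric shape
    descriptors of binary scar masks with per-cluster ANOVA and covariate
    regression, binomial cluster-enrichment probabilities, and a synthetic
    wear-scar cohort generator for validation when retrieval images are
    unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    yaml,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
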
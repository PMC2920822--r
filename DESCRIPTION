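Package: cnamargin
Title: Segmentation-Free Discovery of Recurrent Copy Number Alterations by
    Fused-Lasso Maximum-Margin Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers recurrent copy number alterations (CNAs) in cohorts of
    array-CGH tumor profiles directly from probe-level log-ratios, without a
    per-sample segmentation step.  Each partition of the cohort is obtained by
    maximum-margin clustering with a fused-lasso-constrained linear separator:
    a least-squares classifier whose weight vector is constrained to be sparse
    (L1 budget) and piecewise constant along the genome (distance-weighted
    fusion budget), solved as a quadratic program.  Applied recursively per
    chromosome with orthogonality constraints between successive separators,
    the method yields a hierarchical partition of samples; each split is
    scored by a probe-permutation test on the distance between group median
    profiles.  Cluster centroids are summarized into discrete gain/loss calls
    and pairwise CNA co-occurrence is tested with Fisher's exact test.
    Includes a synthetic aCGH cohort generator with planted events and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    matrixStats,
    optparse,
    quadprog,
    stats,
    utils
Suggests:
    MASS,
    mclust,
    nloptr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
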
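Package: morphosignal
Title: Phylogenetic Signal in Landmark-Based Shape Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based geometric morphometrics coupled with phylogenetic
    comparative tests, built for studies of phylogenetic signal in the shape
    and size of monogenean haptoral anchors and similar small 2-D structures.
    Provides TPS/CSV/XLSX landmark input, chi-squared screening of
    multivariate outliers, Generalized Procrustes Analysis with tangent-space
    projection and centroid size, principal component analysis of shape,
    multivariate regression of shape on log centroid size with permutation
    tests (including phylogenetic independent contrasts for evolutionary
    allometry), squared-change parsimony mapping of a phylogeny into
    morphospace with a tree-length permutation test, the multivariate K
    statistic of phylogenetic signal with its randomization test, and a
    Brownian-motion synthetic-data generator so every stage can be verified
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phytools,
    readxl,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
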
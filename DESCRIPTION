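Package: famrank
Title: Resampling-Consensus Prioritization of Functionally Active Genes
    in Large Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ranking the members of a large, partially
    characterized gene family (such as the plant F-box superfamily) by
    their likely functional activity.  The package combines
    evidence-based group categorization, resampling-based consensus
    k-means clustering of a multi-characteristic feature table, and a
    two-tier resampling-consensus supervised classifier (a small
    multilayer perceptron, with random-forest and support-vector
    alternatives) in which a gene is only called active or inactive when
    it wins a large majority of votes within a round of resampled fits
    and is called consistently across rounds.  A seeded synthetic
    gene-family generator with known ground truth, verification
    statistics (Fisher exact enrichment, Kruskal-Wallis with Dunn post
    hoc tests and Benjamini-Hochberg correction, Welch t tests), and a
    reproducible pipeline driver are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    jsonlite,
    randomForest,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
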
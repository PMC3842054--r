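Package: rankstab
Title: Similarity, Stability and Predictive Performance of Gene Rankers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for comparing biomarker (gene) selection techniques on
    high-dimensional two-class expression data. Implements eight feature rankers
    (chi-squared, information gain, symmetrical uncertainty, gain ratio, OneR,
    ReliefF, linear-SVM weighting and SVM-RFE recursive feature elimination) over
    supervised MDL discretization, gene-set similarity in terms of overlap
    (Jaccard and the chance-corrected Kuncheva index) and of Gene Ontology
    molecular-function semantics (Lin similarity with best-match averaging), and
    a joint subsampling protocol that measures each ranker's selection stability
    and held-out AUC with a linear support vector machine. Includes a synthetic
    expression-data generator with planted markers and redundant correlated
    blocks for end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    foreign,
    kernlab,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
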
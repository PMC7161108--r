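Package: pathembed
Title: Pathway-Level Multi-Omics Embedding and Consensus Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compresses multi-omics features mapping to each biological
    pathway into one per-patient pathway score using a multi-modal sparse
    denoising autoencoder regularized by a sparse group lasso penalty,
    bi-clusters patients and pathways by consensus sparse non-negative
    matrix factorization with cophenetic-correlation rank selection, and
    interprets scores and clusters via Shapley-value feature attribution,
    mutational-burden, survival and clinical-association statistics.
    Includes a synthetic multi-omics data generator with planted patient
    clusters for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    rlang,
    tibble,
    dplyr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    survival
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    yaml,
    withr
Config/testthat/edition: 3
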
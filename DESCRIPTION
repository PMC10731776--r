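Package: mdlink
Title: Microbe-Disease Association Prediction with Multi-Scale Variational
    Graph Autoencoders and Optimal-Transport Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts unknown microbe-disease associations from a sparse
    binary association matrix. Builds multiple similarity networks per axis
    (ontology-based semantic similarity, symptom-profile cosine similarity,
    Gaussian interaction profile kernels, and set-based functional
    similarity), integrates them with similarity network fusion, learns
    per-node latent Gaussian distributions with a multi-scale variational
    graph autoencoder whose prior is enforced through a 2-Wasserstein
    (Sinkhorn) penalty and auxiliary multi-order embedding reconstruction,
    and classifies candidate pairs with gradient-boosted trees under
    stratified cross-validation. Includes a synthetic planted-block
    generator so the whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    clue,
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
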
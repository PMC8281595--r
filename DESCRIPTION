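Package: omicsurv
Title: Ensemble Survival Subtyping from Multi-Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-supervised discovery of survival-ordered molecular subtypes from
    multiple omics layers (e.g. mRNA, miRNA, DNA methylation) sharing a sample
    universe. Each omic layer is rank/correlation-distance normalized, compressed
    with a one-hidden-layer autoencoder (or PCA), and the latent features
    associated with survival in univariate Cox proportional-hazards screens are
    pooled and clustered with a diagonal-covariance Gaussian mixture model.
    Subtypes are relabeled so that label 0 carries the worst survival. A bagging
    ensemble of such models, each fit on a random 80% subsample and filtered on
    survival association, aggregates calibrated subtype probabilities to classify
    new samples - including samples with only a subset of the training omics - and
    supports cross-cohort transfer. Downstream tools rank subtype signature
    features across datasets and build consensus co-expression networks with
    random-walk community detection. Includes a synthetic multi-omic cohort
    generator with known subtype structure and survival signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    cluster
Config/testthat/edition: 3
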
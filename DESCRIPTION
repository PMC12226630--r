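Package: fedproto
Title: Prototype-Guided Federated Learning with Label Denoising for
    Ultrasound Standard-Plane Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for federated learning with
    noisy labels in multi-class ultrasound standard-plane classification.
    Implements contrastive (SimCLR-style, NT-Xent) self-supervised
    pretraining of a small convolutional encoder, embedding-space
    k-nearest-neighbour consensus label cleaning, class-prototype sharing
    with augmented-view majority-vote pseudo-labelling of a small client,
    and FedAvg federated training, together with a synthetic-data module
    that generates learnable four-class plane-like images and
    Gaussian-mixture embeddings with controllable client shift and
    symmetric label noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
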
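Package: macnext
Title: Compact Dual-Activation Convolutional Networks for Bacterial Colony
    Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds, trains and audits MACNeXt, a compact convolutional
    neural network for classifying bacterial colony images from agar
    plates. The architecture combines grouped convolutions, an inverted
    concatenation bottleneck and parallel GELU/ReLU activation branches
    inside residual blocks. The package provides analytic shape tracing
    and closed-form parameter accounting for the network, a full
    CPU training loop (momentum SGD, stratified splits, optional
    class-balanced mini-batches), multiclass confusion-matrix metrics with
    one-vs-rest ROC AUC, and a deterministic synthetic agar-plate colony
    image generator so the whole pipeline can be exercised without access
    to clinical image collections.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    png,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    EBImage,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
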
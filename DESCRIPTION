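Package: stnet
Title: Shape and Texture Two-Stream Networks for Lesion Image Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a two-stream convolutional network for binary lesion
    image recognition that learns shape-biased and texture-biased features
    jointly. The texture stream uses pyramid-grouped convolution (channel
    connectivity transitioning from dense to sparse), the shape stream uses a
    deformable-convolution encoder supervised through an auxiliary mask-decoding
    task, and the two feature maps are fused with channel attention and a
    gradient-scaling layer before classification. Class imbalance is handled by
    an asymmetric focal-style loss with probability transfer. Includes a
    synthetic lesion-image generator with controllable boundary irregularity and
    texture contrast, a seeded training/evaluation pipeline with stratified
    splits and k-fold cross-validation, and a loss-parameter sensitivity
    harness. All convolution, deformable-convolution and transposed-convolution
    kernels, and their reverse-mode gradients, are implemented in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    png,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
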
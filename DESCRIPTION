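Package: stseg
Title: Semi-Supervised Teacher-Student Segmentation for Histopathology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-supervised binary tissue segmentation for stained
    histopathology images. Implements Reinhard color normalization in CIELAB
    space, a lightweight encoder-decoder teacher network trained by iterative
    self-training with thresholded pseudo-labels, Monte Carlo dropout
    uncertainty estimation for pseudo-label quality, and a dual-encoder
    student network with spatial-attention skip connections trained jointly
    with the teacher using binary cross-entropy, consistency regularization
    and a prediction exponential-moving-average loss. Includes a synthetic
    histology-like image generator so the whole pipeline runs end-to-end
    without external data, pixel-wise evaluation metrics, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    jsonlite,
    yaml,
    grDevices,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
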
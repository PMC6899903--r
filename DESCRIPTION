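Package: contactnet
Title: Residue-Residue Contact Prediction with Dilated Residual
    Networks on Alignment-Derived Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Predicts protein residue-residue contacts from multiple
    sequence alignments. Builds a 501-channel pairwise feature tensor
    (sequence profile, predicted secondary structure and solvent
    accessibility striped into 2D maps, mutual information with APC
    correction, joint entropy, a contact-potential map, optional external
    coupling maps, 441 raw covariance channels, sequence-separation and
    bounds channels) and feeds it to a fully convolutional residual
    network with a Maxout input layer and dilated 5x5 convolutions.
    Includes the three training-time augmentations (loop sampling,
    feature interpolation between deep and shallow alignments, 180-degree
    flips), masked binary cross-entropy training with per-example
    gradient accumulation and MCC-based early stopping, effective
    sequence counts by greedy 62 percent-identity clustering, CASP-style
    top-L/k precision evaluation and RR file I/O, and a synthetic family
    generator producing contact-coupled alignments for desk-scale
    experiments.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
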
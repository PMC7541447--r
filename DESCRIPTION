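Package: toeholdr
Title: Design, Quantification and Sequence-to-Function Modelling of Toehold-Switch Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for high-throughput toehold-switch riboregulator studies:
    tiling-based trigger design and first-generation fused-trigger construct
    assembly; flow-seq (sort-seq) read-count quantification into normalized
    ON, OFF and ON/OFF functional values with quality-control tiers; a
    self-contained RNA secondary-structure engine (minimum free energy,
    base-pair probabilities, ensemble defect, kinetic folding trajectories)
    with 30 thermodynamic and 4 kinetic rational features per switch; one-hot
    and directional complementarity-map encodings; a compact neural-network
    stack covering multilayer perceptron, convolutional and recurrent
    sequence-to-function models; and VIS4Map gradient saliency for visualizing
    learned RNA secondary structure. A generative flow-seq simulator with
    known ground truth supports download-free end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
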
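Package: hicdcn
Title: Super-Resolution Enhancement of Hi-C Contact Matrices with a
    Dilated Fully Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enhances low-coverage Hi-C chromatin contact matrices to
    super-resolution using a 10-layer dilated fully convolutional residual
    network trained with a mean-absolute-error loss. Because the network is
    fully convolutional it enhances whole chromosomes of any size in a single
    pass, without tiling. Includes a synthetic Hi-C generator (power-law
    distance decay, TAD blocks, loop anchors, Poisson counts), binomial read
    down-sampling to emulate shallow sequencing, 40x40 patch extraction
    restricted to the sub-2 Mb band, Adam training with best-validation-MAE
    checkpointing, image-quality metrics (MSE, PSNR, global SSIM),
    genomic-distance-stratified Pearson and Spearman correlation tracks, and
    precision/recall/F1 scoring of significant-interaction recovery, with
    readers and writers for sparse triplet, Matrix Market and Fit-Hi-C
    interchange formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    methods,
    optparse,
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
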
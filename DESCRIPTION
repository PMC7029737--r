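Package: cnngwp
Title: Sparse One-Dimensional Convolutional Neural Networks for Genome-Wide Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide prediction of quantitative phenotypes from SNP
    genotypes with a sparse one-dimensional convolutional neural network
    (convolution, max pooling, and an L1-regularized linear output layer),
    trained with the ADAM optimizer. Hyperparameters (number of filters,
    kernel width, L1 penalty) are tuned by Gaussian-process Bayesian
    optimization with an upper-confidence-bound acquisition, and predictions
    are model-averaged over replicate runs. Includes GBLUP (eigendecomposition
    REML ridge on a genomic relationship matrix) and coordinate-descent LASSO
    baselines, mapping of output-layer weights back to SNP coordinates for
    QTL localization, a PLINK RAW (--recode A) reader/writer, and a simulator
    of QTLMAS2010-style genotype/phenotype data with additive, dominance,
    over-/under-dominance and epistatic loci.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    lhs,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
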
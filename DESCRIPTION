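Package: seqrbm
Title: Physicochemical Sequence Encoding and Deep Belief Network
    Classification of Protein Subfamilies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Featurization and classification toolkit for labelled protein
    sequences, built around class C G protein-coupled receptor (GPCR)
    subfamily discrimination. Sequences are converted to numeric form with
    amino-acid physicochemical property indices (AAindex), either
    position-by-position on an alignment (single or combined indices) or
    through alignment-free transforms: amino-acid composition,
    pseudo-amino-acid composition, Haar-wavelet multiscale energy, and
    auto-cross-covariance over the five z-scales. Classification uses a
    stacked Gaussian-Bernoulli restricted Boltzmann machine pretrained by
    contrastive divergence and fine-tuned with a softmax output layer, with
    k-NN, decision-tree, multilayer-perceptron and RBF-SVM baselines.
    Evaluation covers stratified k-fold cross-validation, multi-class
    accuracy, Matthews correlation and balanced error rate, architecture
    grid search, per-index ranking and index-combination search, plus a
    synthetic sequence generator with a tunable class signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    rlang,
    rpart,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
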
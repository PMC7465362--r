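Package: fourmc
Title: DNA N4-Methylcytosine Site Prediction from Sequence Windows with a
    1-D Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies DNA N4-methylcytosine (4mC) sites in fixed-length
    41-nt sequence windows centred on a cytosine. Provides six
    feature-encoding schemes (per-base one-hot, di- and tri-nucleotide
    one-hot, nucleotide chemical property with and without cumulative
    nucleotide frequency, and multivariate mutual information), a small
    two-block 1-D convolutional classifier trained with stochastic gradient
    descent, a 10-fold cross-validation protocol reporting MCC, accuracy,
    sensitivity, specificity and AUC, hyperparameter grid search, and two
    model-interpretation procedures (in silico saturation mutagenesis and
    gradient-times-input saliency maps aggregated by dinucleotide). A
    synthetic motif-planting generator produces labelled benchmarks in the
    same window format so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
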
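Package: breedkit
Title: Breed Identification from SNP Genotypes with Machine Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable toolkit for livestock breed identification from
    SNP genotypes in HapMap format. Covers the full workflow: input
    validation and sample-size power analysis, dimensionality reduction
    (PCA, classical MDS, UMAP) with iterative outlier removal, distance-based
    phylogenetics (neighbor-joining, BioNJ, UPGMA) with SNP-bootstrap
    support, admixture-style ancestry inference with cross-validated choice
    of the number of clusters, discriminative SNP-panel selection
    (chi-square, Fisher's exact test, mutual information, information gain,
    redundancy pruning), multi-class breed classifiers (KNN, random forest,
    SVM, XGBoost) under stratified cross-validation, and assignment of new
    individuals with one-class genotype-likelihood validation and a
    calibrated z-score confidence transform. A Balding-Nichols simulator
    generates multi-breed datasets in the same three input file formats, and
    a command-line entry point ties the stages into reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    uwot,
    clue,
    caret,
    randomForest,
    e1071,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    vegan
Config/testthat/edition: 3
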
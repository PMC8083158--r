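Package: flowpsmm
Title: Treatment-Response Classification for Multiple Myeloma Expression
    Profiles with FloWPS Dynamic Training-Set Trimming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for classifying bortezomib
    treatment response (good vs poor responders) from bulk RNA-seq gene
    counts of multiple myeloma CD138+ cell fractions. Provides a
    negative-binomial synthetic-cohort generator, mapped-reads quality
    filtering, quantile normalization with Ward.D2 clustering and PCA,
    median-of-ratios (size-factor) normalization, leave-one-out core
    marker-gene selection by ROC AUC, the FloWPS floating-window
    projective separator (per-test-sample feature filtering and k-nearest
    -neighbour training-set trimming aggregated over a parameter grid)
    wrapped around five base classifiers (linear SVM, random forest,
    ridge, Bernoulli naive Bayes, multilayer perceptron), leave-one-out
    evaluation (ROC AUC, AUPR, sensitivity/specificity against a
    false-positive/false-negative balance factor), a negative-binomial
    Wald differential-expression test with Benjamini-Hochberg control,
    and multi-dataset DEG-overlap statistics (permutation null, Jaccard
    coefficients, UpSet-style exclusive intersection counts).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    tools,
    MASS,
    nnet,
    e1071,
    randomForest,
    limma,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
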
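Package: gipdr
Title: Drug-Disease Association Prediction with Gaussian Interaction
    Profile Kernels and an Autoencoder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts drug-disease associations for computational drug
    repositioning. Drug and disease descriptors are built from Gaussian
    interaction profile (GIP) kernels over the known association network,
    disease semantic similarity boosted within cohesive modules of a
    weighted disease-sharing network (ClusterONE-style greedy clustering),
    and low-dimensional structural features learned from binary drug
    fingerprints by a single-hidden-layer autoencoder. Pair features are
    optionally refined by batch normalization and a ReLU fully-connected
    layer and classified by a random forest (or, for comparison, an RBF
    support vector machine) under stratified 10-fold cross-validation with
    balanced negative sampling. Includes a seeded synthetic-data generator
    with planted drug/disease module structure, confusion-matrix metrics,
    ROC/AUC, score-distribution summaries, and leave-disease-out drug
    ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    e1071,
    yaml
Suggests: testthat (>= 3.0.0), pROC, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
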
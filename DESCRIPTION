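Package: mrcl
Title: Manifold Regularized Causal Learning
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Semi-supervised classification of ordered variable pairs as
    causal or non-causal from a data matrix together with a partial set of
    known causal labels. Each pair is featurized by a bivariate histogram of
    its standardized, truncated scatter plot; pairs are embedded in a
    similarity graph and labels are propagated to unlabelled pairs by
    Laplacian-regularized least-squares transduction, yielding real-valued
    edge scores and a directed graph that may contain cycles. Includes
    construction of interventional gold standards via robust z-scores,
    random and row-wise label-sampling designs, ROC/AUC evaluation,
    correlation and k-nearest-neighbour baselines, and a linear
    structural-equation simulator emulating gene-knockout studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), pROC, jsonlite
biocViews: Network, GraphAndNetwork, Classification, NetworkInference
Config/testthat/edition: 3
RoxygenNote: 7.3.3
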
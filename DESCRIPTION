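Package: strokesight
Title: Stroke Outcome Modelling from Head CT with Hemisphere-Asymmetry Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A modelling workbench for 90-day functional-outcome (modified
    Rankin Scale) prognosis of ischemic stroke patients from MNI-registered
    head CT. Implements image-only 3D convolutional classifiers (baseline,
    mirror-subtraction, three Siamese hemisphere-merge variants and
    multiple-instance-learning slice-bag models), maximum-intensity-projection
    vessel-occlusion classifiers for CT angiography, and hybrid logistic
    regression models fusing imaging biomarkers with clinical variables,
    together with the stratified-split / cross-validation / paired t-test
    comparison harness. Includes synthetic brain-phantom and cohort generators
    so the full pipeline is testable without patient data. The neural-network
    core (3D/2D convolution, batch normalisation, pooling, backpropagation,
    Adam) is implemented in the package with C++ kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    glmnet,
    lhs,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC
Config/testthat/edition: 3
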
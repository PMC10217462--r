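Package: tensorRad
Title: Tensor Radiomics and Deep Features for PET/CT Outcome Prediction
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Multi-flavour ("tensor") radiomics for co-registered PET/CT
    volumes. Generates 17 image flavours per patient (CT, PET and 15
    image-level fusions: Laplacian and ratio pyramids, separable and
    dual-tree complex wavelets, curvelet- and contourlet-style frequency
    decompositions, sparse-representation and hybrid fusions, cross-bilateral,
    weighted, PCA and HSI fusion), extracts an IBSI-style set of 215
    handcrafted features (79 first-order + 136 3D texture) and 3D
    convolutional-autoencoder bottleneck deep features per flavour, and runs
    conventional (per-flavour) and tensor (cross-flavour) prediction
    pipelines (variance/correlation filtering, PCA or polynomial flavour
    fusion, ANOVA selection, MLP/random-forest/logistic classifiers with
    nine-member ensemble voting) under leakage-free 5-fold nested
    cross-validation, plus an end-to-end 3D CNN baseline. Includes a seeded
    synthetic PET/CT phantom generator whose binary outcome depends jointly
    on CT morphology and PET texture latents, so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    EBImage,
    SummarizedExperiment,
    S4Vectors,
    nnet,
    randomForest,
    glmnet,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    igraph,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
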
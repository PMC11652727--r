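Package: mammoErrors
Title: Radiomic Analysis of Cohort-Specific Reading Errors in Dense Mammograms
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing cohort-specific diagnostic errors in dense
    screening mammography. Pools per-reader annotations into suspicious areas,
    builds false-positive and false-negative response matrices, identifies
    outlying readers by Ward hierarchical clustering of their error profiles,
    labels areas easy or difficult by a median split of false responses, and
    predicts area difficulty from a 201-feature radiomic description
    (first-order, GLCM, GLRLM, GLSM, GLDS, NGTDM, SFM, fractal dimension,
    Laws, Gabor, MR8 and Fourier features) with a nested cross-validated
    random forest using SMOTE oversampling. A synthetic cohort generator
    produces mammogram-like images, lesion truths and simulated reader
    behaviour so the full pipeline can be exercised and validated without
    clinical reading data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    ranger,
    ape,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
biocViews: Software, Classification, FeatureExtraction
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'annotations.R'
    'methods.R'
    'model.R'
    'stats.R'
    'radiomics-firstorder.R'
    'prep.R'
    'radiomics.R'
    'readers.R'
    'pipeline.R'
    'radiomics-filters.R'
    'radiomics-matrices.R'
    'synthetic.R'
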
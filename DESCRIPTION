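Package: xrannotate
Title: Standardized Body-Part Annotation for X-Ray DICOM Archives
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for standardizing heterogeneous body-part descriptions in
    X-ray DICOM archives to a compact SNOMED CT vocabulary organised in a
    three-level anatomical hierarchy. Provides DICOM header extraction and
    PNG conversion, free-text term normalization, a hierarchical multi-level
    classification loss, image preprocessing (Otsu background removal,
    top/bottom-hat contrast enhancement, cartoon-texture decomposition),
    augmentation (random batch transforms, polarity inversion, SMOTE
    oversampling of tail classes), a CPU-scale convolutional training
    harness with stratified cross-validation, evaluation utilities
    (multi-label confusion matrices, t-SNE projections, class activation
    maps), and an annotation-fusion image retrieval index. A synthetic
    radiograph phantom generator makes the whole pipeline testable without
    access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
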
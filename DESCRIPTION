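Package: polypatch
Title: Patch-Based CNN and Texture-Feature Classification of Colonic Polyp Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for two-class (non-neoplastic versus
    neoplastic) classification of endoscopic colonic-polyp images. Provides a
    seeded generator of patient-structured synthetic endoscopy-like texture
    cohorts; flip/rotation data augmentation and grid/random patch extraction
    with balanced sampling; small convolutional neural networks trained from
    scratch on image patches with image-level majority voting; architecture
    replicas of common off-the-shelf CNN feature extractors; multiscale block
    local binary pattern (MB-LBP) and Gabor-wavelet Weibull texture
    descriptors; feature-level fusion with a linear support vector machine;
    leave-one-patient-out and patient-grouped k-fold cross-validation; and
    exact McNemar significance matrices for pairwise classifier comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    e1071,
    EBImage,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
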
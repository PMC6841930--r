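Package: canidmarks
Title: Geometric Morphometrics and Machine-Learning Classification of Canid Tooth Marks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for discriminating the carnivore responsible for tooth marks on
    bone (wolf, dog, fox) from landmark-based geometric morphometrics of tooth-score
    cross-sections (7 landmarks, 2D) and tooth pits (17 landmarks, 3D). Implements
    morphologika and measurement-table I/O, a synthetic three-class tooth-mark
    generator, Generalized Procrustes Analysis with orthogonal tangent projection,
    form-space construction via the natural logarithm of centroid size, thin-plate
    spline warps, the seven groove cross-section measurements including the opening
    angle, PCA with shape/form score bookkeeping, pairwise MANOVA with a
    homogeneity-dependent choice between the Hotelling-Lawley and Wilks statistics,
    and an RBF-kernel support vector machine classification protocol (stratified
    bootstrap, 70:30 split, 10-fold cross-validated random hyperparameter search,
    confusion-matrix evaluation battery).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
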
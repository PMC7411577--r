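Package: cenbi
Title: Vascular-Pattern Analysis and Classification of Laryngeal Lesions in
    Contact Endoscopy Narrow Band Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for automatic benign-versus-malignant classification of
    laryngeal lesions from Contact Endoscopy Narrow Band Imaging (CE-NBI)
    still frames. Enhances sub-epithelial blood vessels with a multiscale
    Hessian-based tubularity filter, segments and skeletonizes the vessel
    network, traces centerline segments, and summarizes the disorder of the
    vasculature in a fixed 24-dimensional bank of direction-consistency and
    curvature features. Four supervised classifiers (polynomial and RBF
    support vector machines, k-nearest neighbours, random forest) operate on
    the feature vectors, with patient-grouped cross-validated grid search for
    hyperparameter tuning. Includes image- and patient-level evaluation
    (sensitivity, specificity, observer-agreement categories,
    per-histopathology misclassification percentages) and a synthetic CE-NBI
    image generator with ground-truth centerlines for longitudinal (LVC) and
    perpendicular (PVC) vascular-change regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    class,
    e1071,
    igraph,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
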
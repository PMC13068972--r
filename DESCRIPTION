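Package: gwovit
Title: Magnification-Aware Breast Histopathology Classification with a
    GWO-Tuned Vision Transformer
Version: 0.1.0
Authors@R:
    person("Histopathology Toolkit", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A tested toolkit for magnification-aware benign/malignant
    classification of H&E breast histopathology images. Provides a four-stage
    stain and color normalization pipeline (CLAHE in LAB space, CDF histogram
    matching, Shades-of-Gray color constancy, and Macenko optical-density stain
    normalization), a per-magnification class-balancing and augmentation engine
    for BreakHis-style directory trees, a configurable compact Vision
    Transformer implemented in base R with manual backpropagation and AdamW,
    a Grey Wolf Optimizer for its hyperparameters, a full evaluation suite
    (confusion matrices, per-class metrics, ROC/AUC, stratified k-fold
    cross-validation, paired t-tests), and a synthetic Beer-Lambert fixture
    generator with known stain ground truth so every component is testable
    without the external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
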
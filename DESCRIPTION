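Package: vitelm
Title: Vision-Transformer Features with an Extreme Learning Machine Head
    for Flat-Foot Radiograph Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Binary classification of lateral foot radiographs as pes planus
    (flat foot, calcaneal tilt angle below 18 degrees) or not, using a
    deterministic Vision Transformer forward pass as a fixed feature
    extractor and an Extreme Learning Machine head whose output weights are
    obtained by Moore-Penrose pseudo-inverse, ridge closed form, or
    mini-batch Adam optimisation with early stopping. Includes the
    patient-grouped five-fold cross-validation protocol with a fixed
    held-out test set, confusion-matrix diagnostic metrics with
    mean/population-standard-deviation aggregation, ROC and precision-recall
    curves, a synthetic foot-radiograph generator for fully offline testing,
    dataset and model input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    patchwork,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
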
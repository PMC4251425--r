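Package: scfwkelm
Title: Subtractive-Clustering Feature Weighting and Kernel Extreme Learning Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-stage diagnostic classification for tabular biomedical data:
    a subtractive-clustering feature-weighting (SCFW) preprocessor that
    rescales each feature by the ratio of its mean to its density-based
    cluster centers, followed by a kernel extreme learning machine (KELM)
    solved in closed form. Includes the original random-hidden-layer extreme
    learning machine and a k-nearest-neighbour classifier as baselines, a
    repeated k-fold cross-validation harness reporting accuracy, sensitivity,
    specificity, AUC, f-measure and Cohen's kappa, an exhaustive log2 grid
    search over the penalty and kernel parameters, loaders for the UCI
    Parkinsons voice dataset dialect and generic labelled CSV tables, and a
    seeded synthetic-data generator emulating the structure of dysphonia
    feature tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
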
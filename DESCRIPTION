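Package: rocsurface
Title: ROC Surfaces, Volume Under the Surface, and FDR-Controlled AUC for
    Class-Skewed Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifier evaluation for heavily class-skewed labeled data, where
    most features belong to the true negative class and the ordinary ROC curve
    and its AUC are dominated by irrelevant operating points. Builds the
    three-dimensional ROC surface over true positive rate, false positive rate
    and true discovery rate (one minus the realized false discovery rate),
    and computes its volume under the surface (VUS, a TDR-weighted AUC) and
    the FDR-controlled AUC (FCAUC, the area under the ROC curve restricted to
    operating points with acceptable FDR). Includes label-permutation
    significance tests for VUS and FCAUC, a rank-based bootstrap test for the
    difference between two ROC surfaces, two-class Gaussian simulation
    utilities for size/power and metric-behaviour studies, delimited-text
    readers and writers, static surface and FDR-coloured ROC plots, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    grDevices,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
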
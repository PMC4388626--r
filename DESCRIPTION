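Package: balancedcs
Title: Balanced Sparse Models for Tight-Frame Compressed-Sensing MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Reconstruction of magnetic resonance images from undersampled
    k-space data under the constrained balanced sparse model, which bridges
    the analysis and synthesis sparse models for tight frames through a
    single balancing parameter. Provides Parseval-tight frame operators
    (shift-invariant wavelets, orthogonal wavelets, translation-invariant
    DCT), variable-density Cartesian undersampling, a constrained split
    augmented Lagrangian solver (C-SALSA-B) with an exact closed-form
    coefficient update, ADMM and accelerated proximal gradient baselines,
    synthetic phantom generation, and experiment runners for balancing
    parameter and sampling-ratio sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    png,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
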
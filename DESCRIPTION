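Package: kinomepcm
Title: Proteochemometric Modelling of Kinase-Inhibitor Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinome-wide proteochemometric modelling of kinase-inhibitor
    binding. Provides six protein-sequence description schemes (z-scales of
    aligned sequences, auto- and cross-covariance transforms and their
    signed maxima, composition/transition/distribution features,
    sequence-order and pseudo-amino-acid descriptors, amino-acid and
    dipeptide composition), ligand-descriptor redundancy pruning,
    block-scaled design-matrix assembly with principal-component
    cross-terms, linear and non-linear regression models (NIPALS PLS with
    and without cross-terms, PLS-DA, epsilon-SVR, distance-weighted k-NN,
    M5-style model trees), and a double (nested) cross-validation and ROC
    evaluation protocol. A synthetic kinase-inhibitor panel generator with
    planted bilinear and cross-term structure makes the full pipeline
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    kernlab,
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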
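Package: tedater
Title: Dating Transposable Element Amplification Bursts and Detecting
    Horizontal Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing transposable element (TE) family
    consensus sequences from genomic copies, measuring within-family
    divergence with the Kimura two-parameter (K80) model, dating
    amplification bursts by divergence ratio against calibration families
    with known age windows, building neighbor-joining trees with bootstrap
    support, and combining consensus identity, relative age and
    presence/absence patchiness (Dollo loss counts) into horizontal-transfer
    verdicts. Includes a K80 burst simulator that generates families of
    known age, rate and transition/transversion bias so every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
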
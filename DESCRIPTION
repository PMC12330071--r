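Package: scplm
Title: Linear Modeling of Mass Spectrometry Single-Cell Proteomics Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Minimal processing and missing-value-aware linear modeling for
    single-cell proteomics (SCP) quantification data. Implements feature and
    cell quality control, PSM/precursor-to-peptide aggregation, per-peptide
    adaptive ridge regression over user-specified cell descriptors, analysis
    of variance, differential abundance analysis with ridge-aware standard
    errors and baseline-intensity-weighted multiple testing, ANOVA-PCA
    component analysis (APCA+) via NIPALS, batch-corrected data
    reconstruction, a ground-truth simulator, and a batch-correction
    benchmark harness (ARI, NMI, purity, silhouette).
License: MIT + file LICENSE
Encoding: UTF-8
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
    cluster,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
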
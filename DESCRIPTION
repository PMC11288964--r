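Package: riboratio
Title: Ribosome Ratio-Omics: Ribosomal Protein Stoichiometry Barcodes from
    Quantitative Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes per-sample ribosomal protein (RP) stoichiometry
    "barcodes" from iBAQ-style protein quantifications: each RP's share of
    the total detected-RP intensity in a sample. Provides the downstream
    inference used in ratio-omics studies of ribosome heterogeneity --
    principal component analysis with iterative SVD imputation of missing
    values and 95% group prediction ellipses, pairwise-complete Pearson
    correlation matrices, hierarchical clustering with correlation distance
    and average linkage, and per-RP differential stoichiometry testing with
    Benjamini-Hochberg correction -- together with a seeded synthetic-data
    generator that emulates bulk and single-cell RP proteomes with planted
    stoichiometry shifts and abundance-dependent dropout, for ground-truth
    validation of every pipeline stage.
License: MIT
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
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
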
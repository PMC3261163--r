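Package: metaproteomr
Title: Faecal Metaproteomics: Target-Decoy Filtering, Protein Grouping,
    Peptide Taxonomy and Microbiota Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for shotgun metaproteomics of
    complex microbial communities such as the human intestinal microbiota.
    Implements target-decoy false discovery rate estimation and filtering of
    peptide-spectrum matches over multiple sequence databases, parsimony-style
    protein grouping with spectral counting, core-metaproteome definition and
    COG functional profiling, lowest-common-ancestor taxonomic assignment of
    tryptic peptides, variance-class correlation analysis of LC-MS feature
    matrices (with hierarchical clustering and PCA), and random-forest
    screening of protein-phylotype associations with Fisher exact genus
    enrichment. Ships a synthetic-data generator with known ground truth that
    emulates a repeated-measures study design (subjects x time points x
    technical replicates) for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    randomForest,
    Biostrings,
    withr
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
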
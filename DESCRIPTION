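Package: hspcproteome
Title: Proteome-Transcriptome Integration for Hematopoietic Stem and
    Progenitor Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for integrating label-free
    proteomics with bulk RNA-seq across hematopoietic stem and progenitor
    cell types. Provides per-replicate total-intensity normalization,
    detection-based presence/absence profiling and discovery-saturation
    curves, classification of genes with mRNA present but protein absent,
    a permutation (label-reshuffling) null distribution with empirical
    confidence intervals for unique mRNA-only counts, top-2.5%
    protein-per-mRNA decoupling selection, miRNA putative-target overlap
    analysis, a from-scratch single-sample gene set enrichment (ssGSEA)
    scorer with Kruskal-Wallis testing and Benjamini-Hochberg control,
    and a seeded synthetic-data generator so every stage runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
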
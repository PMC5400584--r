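Package: domspot
Title: Protein Domain Mutation Mapping, Hotspot Detection and
    Enrichment Analysis for Cancer Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps protein-level somatic mutations from tumour cohorts onto
    protein domain families and multiple-sequence-alignment columns,
    classifies mutations into missense, truncating and in-frame indel
    classes, detects mutationally enriched domain families with a
    chi-square test against a background domain set, identifies positional
    hotspots within family alignments with a binomial tail test, compares
    hotspot landscapes between tumour suppressors, oncogenes and the whole
    gene set, and classifies genes by the 20:20 mutational-pattern rule
    and a cross-validated domain-composition classifier. Includes a
    synthetic-cohort simulator with planted hotspots and enriched families
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr (>= 1.1.0),
    e1071,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
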
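Package: seedshift
Title: Allele-Aware Scanning of miRNA Seed Sites for 3'UTR Variant Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers and prioritizes 3'UTR single-nucleotide variants that
    create, destroy, or substitute canonical miRNA seed-match sites in curated
    miRNA-mRNA pairs. Provides allele-aware scanning for 8mer, 7mer-m8,
    7mer-A1 and 6mer sites, an isoform-wide 3'UTR-exclusivity filter,
    gene and miRNA nomenclature normalization, tissue expression
    normalization with brain-enrichment ranking, variant-centered
    conservation-window extraction, a Fisher exact test for motif presence
    across 3'UTR sets, and a synthetic-data generator that plants
    ground-truth events for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
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
    vcfR,
    withr
Suggests:
    rtracklayer,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
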
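Package: evoaction
Title: Evolutionary Trace and Evolutionary Action Analysis of Coding Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ranks protein residues by evolutionary importance with a
    real-valued evolutionary trace computed over nested phylogenetic
    partitions of a multiple sequence alignment, scores every possible
    missense single-nucleotide substitution of a coding sequence with a
    percentile evolutionary-action score, tiers observed somatic, germline
    and disease variants, and tests observed variant sets against the
    all-substitution background by bootstrap. Cohort-level tools stratify
    tumor samples into mutation-load groups, normalize per-gene mutation
    rates per 100 bp of coding sequence per 1,000 patients, bin genes by
    mutability, summarize gene age (phylostratum) per bin, and compute a
    per-tumor-type selection index with a cross-type confidence bound.
    Residue scores and flagged sites can be mapped onto 3D structures with
    ordered-region enrichment and spatial-clustering statistics. A
    synthetic-data module generates alignments, cohorts, gene ages and
    structures with planted ground truth so the whole pipeline is testable
    offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
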
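Package: peptidetect
Title: Presence, Pseudogenization and Loss of Neuropeptide Genes from
    Genomes and Short-Read Archives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers whether a neuropeptide or receptor gene is present,
    pseudogenized or absent in a species from a genome assembly or an
    unassembled short-read archive.  Provides six-frame translated homology
    search of protein queries against contigs and individual reads with
    spot-level counting, a Poisson coverage model that turns zero detections
    in PCR-free archives into an explicit absence-probability bound,
    rule-based annotation of neuropeptide precursors (signal peptide,
    convertase cleavage sites, C-terminal amidation, paracopy counting and
    family motif classification), frameshift-tolerant protein-to-nucleotide
    alignment for pseudogene lesion detection, tissue expression spot tables,
    and Dollo-parsimony mapping of minimum independent gene-loss events on a
    rooted species tree.  A synthetic-data module generates toy genomes with
    planted multi-exon precursor genes, PCR-free read archives and tissue
    transcript pools so the whole inference chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
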
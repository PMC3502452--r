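Package: kmercomp
Title: Reference-Free Comparative Genomics from Canonical k-mer Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Compares unassembled short-read data from many genomes without a
    reference. Reads (or genome sequences) are converted to canonical k-mer
    frequency tables, k-mers are partitioned into per-genome "tip" sets and
    shared "group" sets with exact membership, reads carrying informative
    k-mers are recruited into small per-genome subsets, and each subset is
    assembled into localized de novo contigs centred on the underlying
    sequence variation. Includes the analytic layer relating variants to
    their k-mer footprint (a SNP spans k k-mers, a novel junction k-1, an
    insertion of length i spans k+i-1), genome-size versus k-mer-diversity
    regression, and contig classification, together with a synthetic
    quadripartite (LSC/IR/SSC) chloroplast-style genome and short-read
    simulator with a ground-truth variant ledger for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringi,
    ggplot2,
    generics,
    withr,
    ape,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
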
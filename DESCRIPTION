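Package: mirforge
Title: Consensus miRNA Catalogue Construction from Multi-Predictor
    Candidates and Small RNA-Seq Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a genome-wide microRNA catalogue by merging candidate
    hairpin predictions from multiple annotation tools, applying a
    reliability filter cascade (homology rescue, score thresholds,
    overlap de-duplication, secondary-structure triage, annotation
    conflicts), verifying candidates against small RNA-seq read profiles
    (rectangular mature-arm blocks separated by a read-free gap),
    calling genomic miRNA clusters and sequence families, predicting
    conserved seed-match target sites in orthologous 3'-UTR alignments
    with hypergeometric enrichment tests under Benjamini-Hochberg FDR
    control, and deriving cross-species expression phylogenies by
    bootstrapped hierarchical clustering. Includes a synthetic-data
    generator with planted ground truth for every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    yaml,
    withr,
    methods,
    ape,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vegan,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
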
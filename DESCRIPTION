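Package: triadpart
Title: Homeolog Expression Partitioning in Allohexaploid Wheat Triads
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies subgenome-resolved expression of homeologous gene
    triplets in allohexaploid wheat RNA-seq. Builds A/B/D triplets from
    pairwise alignment evidence, calls subgenome-diagnostic SNP sites,
    classifies read pairs by their alleles at those sites, allocates
    ambiguous reads proportionally, tests triplets for unequal homeolog
    contribution (exact pairwise tests plus a max/min expression ratio
    gate), partitions stress responses by fold-change ratios between
    homeologs, and predicts HSF/DREB targets by degenerate HSE/DRE
    promoter motif scanning combined with expression-trend matching.
    Includes a synthetic-data generator with full ground truth for
    triplet sequences, paired-end reads, count tables over a
    seven-condition stress design, and motif-planted promoters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
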
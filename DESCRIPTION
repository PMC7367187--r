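Package: introntype
Title: Genome-Wide Classification of U2- and U12-Type Spliceosomal Introns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts introns from genome annotation (GFF3/GTF plus FASTA),
    scores 5' splice-site and branch-point motifs against U2-type and U12-type
    position weight matrices as binary log-ratios, and assigns intron class
    with a linear support vector machine calibrated to a U12-type probability,
    calling U12-type at a 90 percent threshold. Includes downstream
    evolutionary statistics (intron phase bias, -1 exonic nucleotide tables,
    terminal-dinucleotide tables, a binomial test for clustering of U12-type
    introns within genes, splice-variant deduplication), orthologous-intron
    grouping from pairwise protein alignments by maximal-clique listing, and a
    synthetic-genome simulator with planted splice-site motifs for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    e1071,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
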
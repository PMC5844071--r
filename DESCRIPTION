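Package: chipOccupancy
Title: Region-Level ChIP-Seq Occupancy, Intergenic Peak Classification,
    and Validation Assays
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for region-level analysis of ChIP-Seq occupancy in
    gene-dense genomes. Partitions a genome annotation into genic and
    intergenic regions with flanking-gene metadata, computes
    library-normalized IP/INPUT fold enrichment per region with a
    sliding-window strong-peak scan, integrates a gene-expression ranking
    into quantile tiers and cross-tabulates occupancy against expression,
    classifies enriched intergenic regions by flanking-gene orientation
    (promoter, terminator, bidirectional promoter, shared terminator,
    promoter-terminator overlap), performs hypergeometric
    over-representation analysis, and implements ChIP-qPCR
    standard-curve percent-input normalization and histone peptide-array
    specificity ranking. A synthetic-data generator with truth tables
    makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
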
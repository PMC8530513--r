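Package: telomaint
Title: Telomere Content, Allele-Specific Regulation and Dependency
    Associations in Cancer Cell Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates telomere content from whole-genome or whole-exome
    sequencing reads by counting canonical TTAGGG repeat motifs and
    normalizing by GC-band coverage; harmonizes estimates across datasets
    with k-means batch detection and z-score recentering; classifies genes
    as mono- or biallelically expressed from paired DNA/RNA allele counts;
    scores allele-specific methylation of adjacent CpG pairs with the mean
    square contingency coefficient (Phi) and aggregates it over genomic
    regions; associates telomere content and mutations with genome-wide
    CRISPR/RNAi dependency screens, including recursive mutual-top-k
    codependency expansion; and tests CpG-island sets for region-overlap
    and telomere-proximity enrichment with Fisher's exact test. Ships a
    seeded synthetic-data generator with planted ground truth for every
    stage, so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    stringi,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
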
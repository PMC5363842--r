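Package: kzfpclust
Title: Clustering, Evolution and Regulatory Analysis of KRAB-Zinc-Finger Genetic Units
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the genome-wide analysis of KRAB-containing
    poly-zinc-finger protein (KZFP) genes and related genetic units:
    detection of C2H2 zinc-finger motifs, KRAB domains and in-frame
    KRAB-to-ZNF open reading frames; single-linkage clustering of
    repeat-anchored units into genomic clusters; permutation-based
    enrichment statistics for transposable-element composition and
    ChIP-seq peak overlap; per-cluster consensus sequences and
    neighbor-joining similarity trees; zinc-fingerprint diversification
    analysis (tandem duplications, repeated and shared triplet blocks,
    Dollo-style paralog emergence ordering); processed-pseudogene
    (retrocopy) detection; and strand-aware coverage metaprofiles.
    Includes a seeded synthetic-genome generator that emulates the
    cluster organisation, sequence anatomy and regulatory signal
    structure these analyses assume, with ground-truth tables for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
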
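Package: genefamkit
Title: Gene-Family Identification and Molecular-Evolution Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An organism-agnostic toolkit for genome-wide gene-family surveys
    of the kind routinely reported for plant protease and transcription-factor
    families: family-member identification from domain-search evidence with a
    built-in position-specific scoring-matrix scanner, physicochemical
    profiling of proteins (molecular weight, isoelectric point, instability
    index, aliphatic index, GRAVY), duplicate-pair detection with
    tandem/segmental classification, Nei-Gojobori Ka/Ks estimation and
    molecular-clock divergence dating, promoter cis-regulatory element
    scanning against an IUPAC consensus catalogue, neighbor-joining phylogeny
    with bootstrap support and exon-intron structure statistics, expression
    and phenotype formulas (log2 FPKM, 2^-ddCt, survival rate, relative water
    content), and a fully seeded synthetic-data generator that plants ground
    truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
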
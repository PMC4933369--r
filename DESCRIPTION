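Package: bmpchip
Title: Integration of BMP-Pathway ChIP-seq Peaks with Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for deciphering a BMP-responsive transcriptional network from
    ChIP-seq and RNA-seq data: replicate-reproducible peak set construction with
    stringency-based coordinate refinement, time-point and factor combination with
    coordinate precedence rules, TSS-anchored gene-peak association with binomial
    and Pearson chi-square tests over multiple distance windows, multi-dataset
    overlap percentages with insulator and pioneer-factor tracks, DamID-based
    reassignment of candidate phantom peaks, and summit-centred IUPAC consensus
    motif enrichment against control enhancer sets.  A seeded synthetic-data
    generator produces genomes, gene tables, replicate peak sets and overlap
    tracks with planted structure so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    methods,
    jsonlite,
    stats,
    utils
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
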
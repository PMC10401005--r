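Package: panpav
Title: Pangenome Presence/Absence Variation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for map-to-pan pangenome analysis of clade-structured
    plant panels: extraction of non-reference sequence from alignment hits
    (length/identity hit filtering, unaligned-region extraction,
    contamination screening, greedy redundancy removal), depth-adaptive
    gene absence calling from per-base coverage, core/shell/cloud gene
    classification, rarefaction curves, clade and group set algebra,
    Fisher's exact test with FDR control for favorable-gene selection
    scans, and PAV-based clustering (neighbor-joining trees with
    gene-resampling bootstrap, principal component analysis). Includes a
    synthetic-data generator that simulates gene gain/loss on a guide tree
    with ploidy- and domestication-dependent gene content, matched
    coverage tracks, and contig/alignment fixtures with known truth, so
    the whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
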
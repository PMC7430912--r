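Package: desrseq
Title: Three-Way Comparative RNA-Seq Analysis of Genes Differentially
    Expressed in Successful CNS Axon Regeneration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for isolating genes differentially expressed
    in successful regeneration (DESR) from a three-way bulk RNA-seq
    comparison of two axon-regenerative and one non-regenerative central
    nervous system tissue. Covers resolution of duplicate read alignments
    between L and S homeologs of an allotetraploid (Xenopus laevis style)
    genome, FPKM quantification with a density-based active-expression
    threshold, replicate-level differential expression testing on log2
    fold-changes with Benjamini-Hochberg FDR, the direction-aware
    regenerative-intersection filter with opposing-expression calls,
    temporal and overlap summaries, eigenvector PCA of condition profiles,
    and a seeded synthetic allotetraploid experiment generator with planted
    truth so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    GenomicRanges,
    optparse
Config/testthat/edition: 3
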
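Package: smorfcoex
Title: smORF Expression Estimation and Function Prediction from Reannotated
    Microarray Probes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the expression of small open reading frames (smORFs)
    from microarray probe-set signals by exactly matching probe sequences to
    a reference genome, intersecting the matches with smORF coordinates, and
    attributing a weighted share of each probe-set signal to overlapping
    smORFs. Co-expressed known genes are found with a rank-based
    (Spearman) nearest-neighbour search backed by a ball tree over
    standardized rank vectors, and smORF functions are predicted by
    guilt-by-association: per-dataset hypergeometric gene-set enrichment of
    the correlated genes, pooled across datasets, with Benjamini-Hochberg
    false discovery rate control. Includes a synthetic-data generator that
    plants known probe/smORF overlaps and co-expression modules so the whole
    pipeline can be exercised against ground truth, plus a command-line
    interface over the pipeline stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
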
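Package: spatac
Title: Spatial ATAC-Seq Decoding, Fragment Processing and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for microfluidic deterministic-barcoding spatial ATAC-seq.
    Decodes two-round ligation barcodes from raw reads into spatial pixels,
    builds Tn5-shifted deduplicated fragment files, computes per-pixel
    chromatin-accessibility quality metrics (TSS enrichment, FRiP,
    mitochondrial fraction, insert-size distribution), constructs genome-tile
    and gene-score matrices, and runs the downstream stack of iterative
    latent semantic indexing, graph clustering, UMAP, Wilcoxon marker
    detection and backbone pseudotime. Includes a fully seeded synthetic-read
    simulator that emits FASTQ, SAM and ground-truth tables so the complete
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    igraph,
    irlba,
    uwot,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mclust,
    cluster
Config/testthat/edition: 3
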
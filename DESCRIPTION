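Package: spliceflow
Title: Chunked Parallel Spliced Alignment and Binned Genome-Guided
    Transcript Assembly
Version: 0.1.0
Authors@R: person("spliceflow", "maintainers", email = "spliceflow@example.org",
    role = c("aut", "cre"))
Description: A locally parallel, fully testable RNA-seq processing
    pipeline for full-length bulk and single-cell data. Provides an
    alignment-only mode that splits paired FASTQ samples into
    deterministic read chunks, aligns them with a pluggable (built-in
    deterministic) spliced aligner and concatenates per-chunk alignments
    into per-sample files whose record sets are identical to a
    sequential run; a transcript assembly mode that maps alignment
    records into overlapping genomic bins, performs splice-graph
    genome-guided assembly per bin, removes bin-overlap redundancy and
    merges the result with a reference annotation; a six-level
    (base, exon, intron, intron chain, transcript, locus)
    sensitivity/precision evaluator for transcript annotations; and a
    seeded synthetic-data generator producing a small genome,
    multi-isoform annotation and zero-error paired-end reads with exact
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    data.table,
    parallel,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
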
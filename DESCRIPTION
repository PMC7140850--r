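Package: seqmed
Title: Duplicate-Compressed RNA-Seq Quantification with Median-of-Coverage
    Expression and Paired Differential Testing
Version: 0.1.0
Authors@R:
    person("Maintainer", "Seqmed", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a lightweight bulk RNA-seq
    quantification and differential-expression scheme built around unique-read
    compression: reads are end-trimmed, collapsed to distinct sequences with
    per-sample occurrence counts, exact-matched to a reference, assigned a
    single feature identity through a configurable annotation hierarchy, and
    summarised per gene as the median of positional coverage.  Downstream
    steps provide quantile normalization, regularized log2 fold changes,
    paired t-tests with Benjamini-Hochberg false discovery rate control,
    volcano and heatmap transforms, hypergeometric over-representation
    analysis of gene-set collections, and the statistics used for
    proliferation-assay (EdU) and delta-delta-Ct qPCR readouts.  A synthetic
    data generator emulates the paired sham-versus-stimulation design the
    scheme was built for (spiky non-uniform coverage, injected duplicate
    reads, planted fold changes, weakly expressed genes) and supplies ground
    truth for end-to-end recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
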
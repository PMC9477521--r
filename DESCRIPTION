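Package: TEquant
Title: Consensus-Level Quantification of Transposable Element Expression
    from Short-Read RNA-Seq
Version: 1.0.0
Authors@R:
    person("TEquant", "Developers", email = "tequant@example.org",
           role = c("aut", "cre"))
Description: Quantifies transposable element (TE) expression at the
    consensus-sequence level from Illumina-style short RNA-seq reads.
    Reads are aligned against a joint reference of TE consensus sequences
    and annotated coding/non-coding transcripts; only fragments whose
    best-scoring alignments fall exclusively on TE consensus sequences
    are counted, so that reads compatible with exonized TE fragments
    embedded in canonical transcripts never inflate TE counts. Ships a
    deterministic read simulator with per-consensus truth counts, an
    exonized-transcript null benchmark, a SAM ingestion path for external
    aligners, and a command-line interface.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    Rcpp,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
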
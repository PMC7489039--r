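Package: isostruct
Title: Transcript Structure Analysis for Hybrid Long-Read Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing full-length transcript models aligned to a
    genome, as produced by single-molecule (Iso-Seq style) sequencing combined
    with short-read support. Collapses full-length non-chimeric (FLNC)
    transcript models into gene loci and non-redundant isoforms using
    splice-chain identity and overlap rules; classifies loci and isoforms
    against a reference annotation into novel genes, novel isoforms and
    structural categories; enumerates and compares alternative-splicing events
    (intron retention, exon skipping, alternative acceptor/donor sites);
    detects fusion transcripts spanning multiple loci; quantifies expression
    (RPKM), calls differentially expressed genes with t-test plus
    Benjamini-Hochberg control, performs hypergeometric enrichment and qPCR
    2^-ddCt analysis. A synthetic-data generator plants machine-readable
    ground truth (corrupted transcript copies, novel structures, fusions and
    negative-binomial counts with known fold changes) so that every pipeline
    stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
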
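Package: superTx
Title: SuperTranscript Construction by Splice-Graph Assembly of Transcript Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Collapses any set of transcripts per gene into a single
    non-redundant linear reference sequence (a superTranscript) by building a
    base-level splice graph from pairwise transcript alignments, compacting
    it, breaking cycles by node duplication and topologically sorting the
    result. Annotates superTranscripts with exon-like blocks derived either
    from the graph structure or from spliced read alignments, supports
    genome-based construction by flattening an annotation and concatenating
    exonic sequence, merges genome-based superTranscripts with de novo
    contigs, and lifts superTranscript coordinates back to the genome through
    UCSC chain files.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
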
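# superTx

Build **superTranscripts**: one linear reference sequence per gene that
contains every exonic base of the gene's transcripts exactly once (unless a
repeat forces duplication), ordered consistently with all isoforms.

RNA-seq in non-model organisms usually starts from a de novo transcriptome
assembly, where each gene is represented by many redundant, partially
overlapping contigs. That redundancy breaks read assignment, visualisation,
variant calling and exon-level differential-usage counting. A
superTranscript replaces the per-gene contig pile with a single sequence on
which reads can be aligned, blocks counted and variants called, while every
original transcript remains representable as an ordered chain of intervals
on it.

## Method

For each cluster (gene) of transcripts `superTx`:

1. computes all pairwise transcript alignments with a built-in exact-seed
   chain aligner (k-mer seeds, co-linear chaining, gapless blocks; BLAT PSL
   files can be imported instead),
2. builds a directed **splice graph** with one node per transcript base and
   an edge for every consecutive base pair, then merges bases along the
   aligned blocks (union–find, with atomic rejection of blocks that would
   merge two positions of one transcript or different letters),
3. compacts non-branching runs into single nodes,
4. detects directed cycles (caused by repeats in swapped order) and breaks
   each by duplicating its smallest node,
5. topologically sorts the resulting DAG with Kahn's algorithm, using a
   deterministic earliest-input anchor tie-break, and concatenates the node
   sequences into the superTranscript,
6. annotates the result with **blocks** — counting bins delimited either by
   the forks of the transcript paths (*standard*) or by read-derived splice
   junctions supported by ≥ 5 spliced reads (*dynamic*).

When a genome and annotation are available, superTranscripts are instead
built by flattening each gene's exons into disjoint intervals and
concatenating their sequence; transcript coordinates are projected onto the
result and a UCSC chain file is emitted so superTranscript positions (e.g.
variant calls) can be lifted back to genome coordinates. A hybrid mode
aligns de novo contigs to a genome-based superTranscriptome, discards
chimeric contigs (those matching two or more genes), and re-assembles each
gene from its reference sequence plus assigned contigs.

## Worked example

```r
library(superTx)

# two isoforms: exons 1-2-3 and 1-3 of the same gene
gene <- simulate_gene(3, seed = 42)
seqs <- sapply(list(1:3, c(1, 3)), function(ix)
  paste(substring(gene$genome_seq, gene$exons$start[ix] + 1,
                  gene$exons$end[ix]), collapse = ""))
cl <- st_cluster("demo", c("full", "skip"), seqs)
st <- assemble_cluster(cl)
st
#> super_transcript 'demo': 490 bp, 2 transcript(s)
standard_blocks(st)
#>   st_start st_end     kind
#> 1        0     98 standard
#> 2       98    376 standard
#> 3      376    490 standard
st$paths$skip
#>   st_start st_end
#> 1        0     98
#> 2      376    490
```

The superTranscript carries all 490 exonic bases once; the three blocks are
the counting bins delimited by the skipped exon (positions 98–376), and the
`skip` isoform's path jumps over it. `path_sequence(st, "skip")` reproduces
the input transcript exactly.

A command-line wrapper over the same functions is installed at
`inst/cli/superT.R` (subcommands `build`, `annotate`, `genome`, `lift`,
`hybrid`, `fixtures`).

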
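---
title: "Constructing superTranscripts: model, parameters and design choices"
author: "superTx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing superTranscripts: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The representation

A *superTranscript* is a single linear sequence per gene containing every
exonic base of the gene's transcripts, ideally exactly once, ordered so
that every isoform appears as an ordered chain of non-overlapping intervals
on it. It is not a biological molecule; it is a reference layout. Its value
is practical: reads can be aligned to one sequence per gene instead of a
redundant contig set, exon-level counting bins ("blocks") can be defined on
it, and positions on it can be lifted to genome coordinates when a genome
exists.

`superTx` builds superTranscripts from any transcript set — de novo
assemblies, curated annotations, or a mixture — given only a FASTA of
transcripts and a two-column table assigning each transcript to a cluster
(gene). Clustering itself (e.g. Corset) is out of scope and consumed as
input.

## The assembly model

The core is a base-level splice graph per cluster.

**Pairwise alignment.** All unordered transcript pairs within a cluster
(capped, see below) are aligned with a built-in aligner: maximal exact
matches of length ≥ `min_block_len` are found from shared k-mers (seeds,
`k = 11` by default, mirroring the tile size of the external local aligners
typically used for this task), then chained by a quadratic dynamic program
that maximises matched bases over strictly co-linear blocks. Two blocks may
overlap by a few bases when an exact match runs past a splice junction into
a coincidentally identical prefix of the next exon; the DP resolves this by
trimming the later block's start on both coordinates, which keeps blocks
exact. Both orientations are evaluated and the better strand kept. Because
an external local aligner reports *several* alignments per pair (not one),
`cluster_alignments()` likewise peels off all disjoint local chains per
pair in decreasing score order; this is what allows two copies of a shared
repeat in swapped order to both be merged, the situation that creates
cycles. Imported 21-column PSL alignments can be used verbatim instead.

Alignment records store, for strand `-`, query coordinates in the forward
frame and target coordinates in the reverse-complemented target frame, so
blocks increase strictly on both axes in either orientation. `min_block_len`
and `k` are capped at the shorter sequence length so that full-length
identity between short sequences is always detected.

**Orientation.** De novo contigs arrive in arbitrary orientations. Within
each connected component of the alignment graph, orientation is propagated
from the lowest-input-rank transcript by breadth-first search: a transcript
whose best alignment toward the component anchor is on `-` is
reverse-complemented, and alignments are recomputed. Transcripts with no
alignment are left unchanged.

**Graph build and merge.** The base graph has one node per transcript base
and an edge to each base's successor. Aligned blocks are merged base-by-base
with a union–find. A whole block is rejected atomically if applying it would
(i) put two distinct offsets of one transcript into one node — the
single-placement rule that makes internal repeats safe and guarantees
reconstruction — or (ii) unify different base letters (possible only for
imported alignments with mismatches; internal blocks are exact). Alignments
are processed in deterministic pair order, so merge conflicts resolve
identically on every run.

**Compaction.** Maximal non-branching runs — interior in-degree one,
out-degree one, and identical member continuity (no transcript may end or
start mid-run) — collapse into single nodes carrying a multi-base sequence.

**Cycle breaking.** Cycles arise when shared sequence occurs in different
orders across transcripts. While a cycle exists, the smallest node of the
detected cycle (ties by earliest anchor, i.e. smallest (input rank, offset)
among its members) is duplicated: the occurrences entering it via the
cycle's incoming edge move to the duplicate along with their outgoing
continuation. This removes the detected cycle's closing edge while keeping
every transcript walk intact. On adversarial repeat-dense inputs fresh
duplicates can keep spawning new cycles; past a soft iteration cap the
smallest *shared* cycle node is instead split fully into per-occurrence
copies, which strictly reduces node sharing and guarantees termination. A
hard cap (total base count plus the occurrence count) turns pathological
non-termination into an error rather than a hang.

**Topological sort.** Kahn's algorithm yields a non-unique order; a
reproducible reference needs a total one. Among ready nodes we emit the one
with the smallest (component anchor, node anchor) key: disconnected
components (transcripts sharing no alignment) come out contiguous, ordered
by their earliest-input anchor, and ties inside a component go to the
earliest (input rank, offset) member. Transcript paths are then read off by
mapping each walk to intervals on the concatenated sequence; adjacent
intervals merge. Assembly verifies, before returning, that every used
transcript's path spells its (orientation-normalised) input sequence
exactly.

**Transcript cap.** Clusters are truncated to their first 50 transcripts by
input order (`max_transcripts`); the splice graph grows quadratically in
pairwise alignments, and in practice few genes exceed the cap. Skipped
transcripts are reported, never silently dropped.

## Block annotation

*Standard blocks* are derived from the transcript paths: the boundary set is
{0, L} plus every path-interval endpoint, which after serialisation equals
the fork/divergence set of the splice graph (paths are the graph's walks).
Adjacent exons always spliced together therefore collapse into one block.

*Dynamic blocks* come from reads instead: every `N` operation in a CIGAR
against the superTranscript defines a junction; junctions whose flanking
matched run is shorter than `min_overhang` (default 12, mirroring the
common splice-junction overhang filter of spliced aligners) are ignored,
and only junctions supported by at least `min_support` reads (default 5
spliced reads) contribute boundaries. Support counts each alignment
record's N operations individually; a read crossing the same junction twice
through two N operations counts twice (degenerate, documented). Dynamic
mode uses reads alone and does not intersect with graph-derived boundaries.
Both block sets always partition [0, L); raising `min_support` can only
remove boundaries.

## Genome mode

With a genome FASTA and a GTF/GFF whose exons carry `gene_id` and
`transcript_id`, each gene's exons are flattened into disjoint intervals
(IRanges reduction; touching intervals merge) and their sequence
concatenated. Minus-strand genes emit the reverse complement of the
concatenation so the superTranscript reads 5'→3'; all block and path
coordinates are expressed in that final frame. Transcript exons (each
necessarily contained in one union interval) are projected through the
cumulative-offset map and merged when adjacent. Each union interval yields
one ungapped segment of a UCSC chain record (target = superTranscript,
query = genome, reversed-query frame for minus strands); `lift()` and
`lift_inverse()` map positions through the containing segment, returning an
explicit "unmapped" result — not an error — for positions outside every
segment, as happens for de novo superTranscripts whose novel sequence has
no genomic home. Chains can also be derived from superTranscript-vs-genome
alignments, taking the best-scoring hit after excluding alternative-locus
chromosomes (default pattern `_alt$`). Genes are processed independently;
exons shared between overlapping gene annotations are duplicated across
their genes.

## Hybrid merging

To supplement a genome-based superTranscriptome with de novo contigs, each
contig is aligned to the reference superTranscripts; a hit qualifies at
`min_score` 200 matched bases and `min_identity` 0.98 (the usual assignment
settings for this task). Contigs with one qualifying target join its
cluster; contigs matching two or more are discarded as chimeric — only
qualifying hits count toward the multi-hit rule; sub-threshold hits do not
make a contig chimeric. Unassigned contigs can be routed through a second
reference (e.g. another species' superTranscriptome) and are dropped if
they fail both passes. Each cluster is then re-assembled with the genome
based superTranscript at input rank 0, so shared sequence keeps its
genome-based order and every reference base survives into the merged
result. `coverage_report()` measures, per source label, the fraction of
merged superTranscript bases covered by that source's paths, and the
fraction covered by no reference source (novel-sequence candidates).

## The synthetic generator and what the tests show

The generator plants genes with 1–5 exons of 50–300 bp separated by
20–100 bp introns, and 1–8 isoforms per gene, each a subset of exons with
the first and last always kept and every exon kept by at least one isoform
— compact vertebrate-like gene models whose exon union is recoverable from
the transcripts alone. All generators are pure functions of their seed.

One deliberate construction detail: junction-adjacent guard bases. With
fully random exon sequence, an exact alignment legitimately extends one to
three bases past a splice junction whenever two alternative successor
exons happen to share their first base(s); the gene model's exon-union
length then differs from the true sequence-level non-redundant length by a
few bases, and "superTranscript length equals exon-union length" stops
being a well-defined truth. The generator therefore gives every possible
junction-entry exon a distinct first base and every junction-exit exon a
distinct last base (satisfiable for up to five exons on a four-letter
alphabet), making the union length exact by construction. Real data has no
such guarantee: on real assemblies, boundary-coincident bases will
occasionally be shared between blocks, shortening the superTranscript by a
few bases relative to the annotation union without affecting transcript
reconstruction.

The generator also does not emulate sequencing error, expression levels,
alternative transcription starts/ends inside exons, trans-splicing, or
fragmented/misassembled contigs. Passing tests therefore demonstrate the
correctness of the graph algebra (reconstruction, non-redundancy,
determinism, cycle handling, coordinate arithmetic), not robustness to
assembly artefacts.

Test and measurement problem sizes were chosen to exercise the properties
at meaningful scale while keeping a full run inside a few minutes on one
CPU: 200 genes for the reconstruction/non-redundancy suite, 100 two-strand
genes for genome mode, 150 random micro-clusters (≤ 3 transcripts, ≤ 20 bp,
3-letter alphabet to force repeat collisions) for the exhaustive
admissibility check.

## Numerical and degenerate-input choices

- Coordinates are 0-based half-open everywhere internally; conversion to
  1-based inclusive happens once, at the GFF/chain boundary.
- All tie-breaks (chain DP, cycle-node selection, Kahn) are resolved by
  deterministic keys (sorted order, anchors), so identical inputs give
  byte-identical FASTA/GFF output, independent of the worker count used
  for per-cluster parallelism.
- `N` bases are legal, participate in exact matching only against `N`, and
  are never merged with other letters; characters outside `A,C,G,T,N` are
  normalised to `N` with a warning, `U` silently becomes `T`.
- A cluster with one transcript, or with transcripts sharing no alignment,
  assembles without error (identity, respectively anchor-ordered
  concatenation).
- Empty sequences are rejected at construction; alignment of sequences
  shorter than the seed simply finds nothing.
- The seed-and-chain aligner equals the unrestricted optimal co-linear
  chain score whenever its candidate blocks do not overlap — the regime of
  the production parameters (`k = 11`, `min_block_len = 20`). With heavily
  overlapping repeat blocks at tiny `min_block_len` it can score below the
  unrestricted optimum, which may trim a predecessor's end — a
  configuration seed-chaining does not represent. It never scores above
  it.

## Known limitations

- Gapless blocks only: indels inside an aligned region split it into
  separate blocks and the intervening bases stay unmerged. Affine-gap and
  translated alignment are out of scope.
- The aligner is for transcript-scale sequences, not genome-scale search.
- Chimeric input transcripts (fusions) are not detected within a cluster;
  the chimera rule applies only to hybrid contig assignment.
- Block-level statistics (count tables, differential usage testing) are
  downstream of this package and not included.
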
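# Hybrid merging: assign de novo contigs to genome-based superTranscripts by
# alignment, discard chimeras, rebuild each cluster with the splice-graph
# core, and report per-source base coverage.

#' Align contigs against a reference superTranscriptome
#'
#' Convenience wrapper running the internal aligner for every
#' contig-vs-reference pair (both strands).
#'
#' @param contigs named character vector of contig sequences.
#' @param references named character vector of reference superTranscript
#'   sequences.
#' @param min_block_len,k aligner parameters.
#' @return List of [st_alignment] (query = contig, target = reference).
#' @export
align_contigs <- function(contigs, references, min_block_len = 20L, k = 11L) {
  out <- list()
  for (ci in names(contigs)) {
    for (ri in names(references)) {
      al <- align_pair(contigs[[ci]], references[[ri]],
                       min_block_len = min_block_len, k = k,
                       query_id = ci, target_id = ri)
      if (!is.null(al)) out[[length(out) + 1L]] <- al
    }
  }
  out
}

#' Assign contigs to reference superTranscripts
#'
#' A hit qualifies when its score (matched bases) reaches `min_score` and
#' its identity reaches `min_identity` (defaults mirror common BLAT
#' assignment settings, minScore 200 / minIdentity 0.98). Contigs with
#' exactly one qualifying target are assigned to it; contigs matching two or
#' more targets are discarded as chimeric; contigs with none are unassigned
#' and may be routed to a secondary reference pass.
#'
#' @param alignments list of [st_alignment] (query = contig).
#' @param min_score minimum matched bases of a qualifying hit.
#' @param min_identity minimum identity of a qualifying hit.
#' @param contig_ids optional full contig universe (so contigs with no
#'   alignment at all appear among the unassigned).
#' @return List with `assigned` (named character: contig -> target),
#'   `discarded_chimeric` and `unassigned` (character vectors).
#' @export
assign_contigs <- function(alignments, min_score = 200L, min_identity = 0.98,
                           contig_ids = NULL) {
  qual <- Filter(function(a) a$score >= min_score &&
                   a$identity >= min_identity, alignments)
  qdf <- if (length(qual)) {
    unique(data.frame(
      contig = vapply(qual, `[[`, character(1), "query_id"),
      target = vapply(qual, `[[`, character(1), "target_id")))
  } else {
    data.frame(contig = character(), target = character())
  }
  all_ids <- unique(c(contig_ids,
                      vapply(alignments, `[[`, character(1), "query_id")))
  nhit <- table(factor(qdf$contig, levels = unique(qdf$contig)))
  single <- names(nhit)[nhit == 1L]
  multi <- names(nhit)[nhit >= 2L]
  assigned <- stats::setNames(qdf$target[match(single, qdf$contig)], single)
  unassigned <- setdiff(all_ids, c(single, multi))
  list(assigned = assigned,
       discarded_chimeric = sort(multi),
       unassigned = sort(unassigned))
}

#' Rebuild clusters of genome-based superTranscript plus assigned contigs
#'
#' For every reference superTranscript with at least one assigned contig (or
#' alone), a cluster is formed with the reference at input rank 0 — the
#' anchor, so shared sequence keeps its genome-based order — and assembled
#' with [assemble_cluster()].
#'
#' @param references named character vector of genome-based superTranscript
#'   sequences.
#' @param assignment `assigned` map from [assign_contigs()].
#' @param contigs named character vector of contig sequences.
#' @param ... passed to [assemble_cluster()].
#' @return Named list of [super_transcript]; each carries a `source_of`
#'   attribute mapping member ids to `"genome"` or `"denovo"`.
#' @export
rebuild <- function(references, assignment, contigs, ...) {
  out <- list()
  for (rid in sort(names(references))) {
    members <- names(assignment)[assignment == rid]
    ids <- c(rid, members)
    seqs <- c(references[[rid]], unname(contigs[members]))
    cl <- st_cluster(rid, ids, seqs)
    st <- assemble_cluster(cl, ...)
    attr(st, "source_of") <- stats::setNames(
      c("genome", rep.int("denovo", length(members))), ids)
    out[[rid]] <- st
  }
  out
}

#' Per-source base coverage of a merged superTranscript
#'
#' For each source label, the fraction of superTranscript bases lying in at
#' least one path interval of that source's member transcripts; also reports
#' the fraction covered by none of the `reference_sources` (novel-sequence
#' candidates contributed only by other sources).
#'
#' @param st a [super_transcript].
#' @param source_of named character vector mapping member transcript ids to
#'   source labels (defaults to the `source_of` attribute set by
#'   [rebuild()]).
#' @param reference_sources labels counted as genome-based for the novel
#'   fraction (default `"genome"`).
#' @return List with `fractions` (named numeric per source) and
#'   `novel_fraction`.
#' @export
coverage_report <- function(st, source_of = attr(st, "source_of"),
                            reference_sources = "genome") {
  if (is.null(source_of)) stop("no source labels available")
  L <- nchar(st$sequence)
  cov_of <- function(ids) {
    ids <- intersect(ids, names(st$paths))
    if (!length(ids)) return(logical(L))
    covered <- logical(L)
    for (tx in ids) {
      p <- st$paths[[tx]]
      for (i in seq_len(nrow(p)))
        covered[(p$st_start[i] + 1L):p$st_end[i]] <- TRUE
    }
    covered
  }
  sources <- sort(unique(unname(source_of)))
  fractions <- vapply(sources, function(s)
    sum(cov_of(names(source_of)[source_of == s])) / L, numeric(1))
  ref_cov <- cov_of(names(source_of)[source_of %in% reference_sources])
  list(fractions = fractions, novel_fraction = sum(!ref_cov) / L)
}

#' Full hybrid merge pipeline
#'
#' Aligns contigs to the primary reference, assigns them (chimeras
#' discarded), optionally routes unassigned contigs through a secondary
#' reference pass, and rebuilds every cluster. Contigs failing both passes
#' are dropped.
#'
#' @param references primary (genome-based) reference sequences, named.
#' @param contigs de novo contig sequences, named.
#' @param secondary optional secondary reference sequences for the rescue
#'   pass (e.g. another species' superTranscriptome).
#' @param min_score,min_identity qualifying-hit thresholds.
#' @param ... passed to [assemble_cluster()] via [rebuild()].
#' @return List with `sts` (merged superTranscripts), `assignment`
#'   (primary-pass result), `secondary_assignment` (or `NULL`) and
#'   `dropped` (contig ids failing all passes).
#' @export
hybrid_merge <- function(references, contigs, secondary = NULL,
                         min_score = 200L, min_identity = 0.98, ...) {
  alns <- align_contigs(contigs, references)
  asg <- assign_contigs(alns, min_score = min_score,
                        min_identity = min_identity,
                        contig_ids = names(contigs))
  sec <- NULL
  if (!is.null(secondary) && length(asg$unassigned)) {
    alns2 <- align_contigs(contigs[asg$unassigned], secondary)
    sec <- assign_contigs(alns2, min_score = min_score,
                          min_identity = min_identity,
                          contig_ids = asg$unassigned)
  }
  dropped <- c(asg$discarded_chimeric,
               if (is.null(sec)) asg$unassigned
               else c(sec$discarded_chimeric, sec$unassigned))
  sts <- rebuild(references, asg$assigned, contigs, ...)
  list(sts = sts, assignment = asg, secondary_assignment = sec,
       dropped = sort(unique(dropped)))
}
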
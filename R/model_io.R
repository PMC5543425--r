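# FASTA + cluster-table input and FASTA/GFF3 superTranscriptome output.

header_tokens <- c("transcript_id", "transcript", "id", "contig", "contig_id",
                   "query", "name")

#' Read transcripts grouped into clusters
#'
#' Reads a transcript FASTA and a Corset-style two-column tab-separated
#' cluster table (`transcript_id<TAB>cluster_id`) and returns the transcripts
#' grouped by cluster, preserving input order within each cluster. Sequences
#' are upper-cased and `U` converted to `T`. Blank lines in the cluster table
#' are ignored; a first line whose first field is a recognisable column
#' header (e.g. `transcript_id`) is skipped.
#'
#' @param fasta_path path to the transcript FASTA.
#' @param cluster_path path to the cluster table.
#' @return Named list of [st_cluster] objects, in order of first appearance
#'   of each cluster in the table.
#' @export
read_transcripts <- function(fasta_path, cluster_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate transcript id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqmap <- stats::setNames(as.character(seqs), ids)

  lines <- readLines(cluster_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("cluster file is empty: ", cluster_path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield < 2L))
    stop("cluster file line ", which(nfield < 2L)[1L],
         " does not have two tab-separated columns")
  tx <- trimws(vapply(fields, `[[`, character(1), 1L))
  cl <- trimws(vapply(fields, `[[`, character(1), 2L))
  if (tolower(tx[1L]) %in% header_tokens) {
    tx <- tx[-1L]; cl <- cl[-1L]
    if (length(tx) == 0L) stop("cluster file has a header but no data rows")
  }
  if (anyDuplicated(tx))
    stop("duplicate transcript id(s) in cluster file: ",
         paste(unique(tx[duplicated(tx)]), collapse = ", "))
  missing <- setdiff(tx, ids)
  if (length(missing))
    stop("transcript(s) in cluster file absent from FASTA: ",
         paste(missing, collapse = ", "))
  unused <- setdiff(ids, tx)
  if (length(unused))
    warning(length(unused), " FASTA record(s) absent from cluster file were dropped: ",
            paste(utils::head(unused, 5L), collapse = ", "),
            if (length(unused) > 5L) ", ...")

  idx <- split(seq_along(tx), factor(cl, levels = unique(cl)))
  clusters <- lapply(names(idx), function(cid) {
    i <- idx[[cid]]
    st_cluster(cid, tx[i], unname(seqmap[tx[i]]))
  })
  stats::setNames(clusters, names(idx))
}

# Build the GRanges feature set for one superTranscript (1-based inclusive).
st_features <- function(st, blocks) {
  L <- nchar(st$sequence)
  cid <- st$cluster_id
  if (!is.null(blocks) && nrow(blocks) > 0L && any(blocks$st_end > L))
    stop("block exceeding sequence length for superTranscript '", cid, "'")
  gr <- list()
  gr[[1L]] <- GenomicRanges::GRanges(
    seqnames = cid, ranges = IRanges::IRanges(1L, L), strand = "+",
    source = "superTx", type = "gene", ID = cid, Parent = NA_character_)
  if (!is.null(blocks) && nrow(blocks) > 0L) {
    blocks <- blocks[order(blocks$st_start), , drop = FALSE]
    kind <- if ("kind" %in% names(blocks)) as.character(blocks$kind) else "standard"
    gr[[2L]] <- GenomicRanges::GRanges(
      seqnames = cid,
      ranges = IRanges::IRanges(blocks$st_start + 1L, blocks$st_end),
      strand = "+", source = kind, type = "exon",
      ID = sprintf("%s:block:%d", cid, seq_len(nrow(blocks))),
      Parent = cid)
  }
  txs <- sort(names(st$paths))
  for (tx in txs) {
    p <- st$paths[[tx]]
    gr[[length(gr) + 1L]] <- GenomicRanges::GRanges(
      seqnames = cid,
      ranges = IRanges::IRanges(min(p$st_start) + 1L, max(p$st_end)),
      strand = "+", source = "superTx", type = "match",
      ID = tx, Parent = NA_character_)
    gr[[length(gr) + 1L]] <- GenomicRanges::GRanges(
      seqnames = cid,
      ranges = IRanges::IRanges(p$st_start + 1L, p$st_end),
      strand = "+", source = "superTx", type = "match_part",
      ID = sprintf("%s:part:%d", tx, seq_len(nrow(p))),
      Parent = tx)
  }
  do.call(c, gr)
}

#' Write a superTranscriptome as FASTA + GFF3
#'
#' FASTA records are named by `cluster_id`; the GFF3 uses the `cluster_id` as
#' seqid with 1-based inclusive coordinates. Per superTranscript a `gene`
#' feature spans the sequence, each annotation block is an `exon` feature
#' (the GFF source column carries the block kind, `standard` or `dynamic`),
#' and each transcript path is a `match` feature with one `match_part`
#' feature per path segment sharing the transcript id as `Parent`. Records
#' are ordered lexicographically by cluster id, then coordinate, so two runs
#' on identical input produce byte-identical files.
#'
#' @param sts list of [super_transcript] objects.
#' @param annotations named list (by cluster id) of block data.frames with
#'   columns `st_start`, `st_end` and optionally `kind`; `NULL` entries get
#'   no exon features.
#' @param fasta_out,gff_out output paths.
#' @return Invisibly, the (sorted) vector of cluster ids written.
#' @export
write_supertranscriptome <- function(sts, annotations = NULL,
                                     fasta_out, gff_out) {
  ids <- unname(vapply(sts, `[[`, character(1), "cluster_id"))
  if (anyDuplicated(ids)) stop("duplicate cluster ids among superTranscripts")
  ord <- order(ids, method = "radix")
  sts <- sts[ord]; ids <- ids[ord]
  extra <- setdiff(names(annotations), ids)
  if (length(extra))
    stop("annotation(s) referencing unknown superTranscript(s): ",
         paste(extra, collapse = ", "))
  dna <- Biostrings::DNAStringSet(vapply(sts, `[[`, character(1), "sequence"))
  names(dna) <- ids
  Biostrings::writeXStringSet(dna, fasta_out)
  feats <- lapply(sts, function(st) st_features(st, annotations[[st$cluster_id]]))
  feats <- lapply(feats, function(x) {
    GenomeInfoDb::seqlevels(x) <- ids
    x
  })
  all <- do.call(c, unname(feats))
  GenomeInfoDb_safe_seqlengths(all, stats::setNames(nchar(dna), ids))
  rtracklayer::export(all, gff_out, format = "gff3")
  invisible(ids)
}

# Attach seqlengths without importing GenomeInfoDb directly (it is loaded by
# GenomicRanges); failures here are cosmetic only.
GenomeInfoDb_safe_seqlengths <- function(gr, lens) {
  try({
    GenomeInfoDb::seqlengths(gr) <- lens[GenomeInfoDb::seqlevels(gr)]
  }, silent = TRUE)
  gr
}

#' Read a superTranscriptome back from FASTA + GFF3
#'
#' Inverse of [write_supertranscriptome()]: reconstructs the
#' [super_transcript] objects (sequences and transcript paths from
#' `match_part` features) and the block annotations (`exon` features).
#'
#' @param fasta_path,gff_path files written by [write_supertranscriptome()].
#' @return List with elements `sts` (named list of [super_transcript]) and
#'   `blocks` (named list of block data.frames with 0-based half-open
#'   `st_start`/`st_end` and `kind`).
#' @export
read_supertranscriptome <- function(fasta_path, gff_path) {
  dna <- Biostrings::readBStringSet(fasta_path)
  names(dna) <- sub("\\s.*$", "", names(dna))
  gff <- rtracklayer::import(gff_path, format = "gff3")
  sts <- list(); blocks <- list()
  for (cid in sort(names(dna))) {
    f <- gff[as.character(GenomicRanges::seqnames(gff)) == cid]
    part <- f[f$type == "match_part"]
    paths <- list()
    if (length(part)) {
      par <- as.character(S4Vectors::unstrsplit(part$Parent, ","))
      for (tx in unique(par)) {
        p <- part[par == tx]
        p <- p[order(GenomicRanges::start(p))]
        paths[[tx]] <- data.frame(st_start = GenomicRanges::start(p) - 1L,
                                  st_end = GenomicRanges::end(p))
      }
    }
    ex <- f[f$type == "exon"]
    if (length(ex)) {
      ex <- ex[order(GenomicRanges::start(ex))]
      blocks[[cid]] <- data.frame(
        st_start = GenomicRanges::start(ex) - 1L,
        st_end = GenomicRanges::end(ex),
        kind = as.character(ex$source))
    }
    sts[[cid]] <- super_transcript(cid, as.character(dna[[cid]]), paths)
  }
  list(sts = sts, blocks = blocks)
}
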
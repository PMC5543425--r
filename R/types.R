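#' @keywords internal
"_PACKAGE"

# Internal coordinate convention: 0-based half-open everywhere; conversion to
# 1-based inclusive happens only at the GFF/chain boundary.

#' Construct a transcript cluster
#'
#' A cluster groups the transcripts assigned to one gene (e.g. by Corset) and
#' is the assembly unit for one superTranscript. Transcript order is
#' significant: `input_rank` (0-based, dense) records order of appearance and
#' drives both the default 50-transcript cap and all deterministic
#' tie-breaking downstream.
#'
#' @param cluster_id single string naming the cluster/gene.
#' @param ids character vector of unique transcript ids.
#' @param seqs character vector of DNA sequences (same length as `ids`).
#'   Sequences are upper-cased, `U` is converted to `T`; characters outside
#'   `A,C,G,T,N` are replaced by `N` with a warning.
#' @return An object of class `st_cluster`: a list with elements
#'   `cluster_id`, `ids`, `seqs` and `ranks` (0-based input ranks).
#' @export
st_cluster <- function(cluster_id, ids, seqs) {
  stopifnot(is.character(cluster_id), length(cluster_id) == 1L,
            length(ids) == length(seqs), length(ids) >= 1L)
  if (anyDuplicated(ids))
    stop("duplicate transcript id(s) in cluster '", cluster_id, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- normalize_dna(seqs)
  if (any(nchar(seqs) < 1L))
    stop("empty transcript sequence in cluster '", cluster_id, "'")
  structure(list(cluster_id = cluster_id,
                 ids = as.character(ids),
                 seqs = seqs,
                 ranks = seq_along(ids) - 1L),
            class = "st_cluster")
}

#' @export
print.st_cluster <- function(x, ...) {
  cat("st_cluster '", x$cluster_id, "': ", length(x$ids),
      " transcript(s), lengths ", paste(nchar(x$seqs), collapse = ","),
      "\n", sep = "")
  invisible(x)
}

#' Construct a pairwise alignment record
#'
#' Gapless co-linear block pairs linking positions of two transcripts
#' (BLAT/PSL-like). Blocks are 0-based half-open triples
#' `(q_start, t_start, length)`, strictly increasing in both coordinates.
#' For strand `"-"`, `q_start` refers to the forward query frame and
#' `t_start` to the reverse-complemented target frame, so co-linearity holds
#' on both axes.
#'
#' @param query_id,target_id transcript ids.
#' @param strand `"+"` or `"-"`.
#' @param blocks data.frame with integer columns `q_start`, `t_start`, `length`.
#' @param identity fraction of matching aligned bases in `[0,1]`.
#' @param score integer; matched bases of the chain.
#' @return An object of class `st_alignment`.
#' @export
st_alignment <- function(query_id, target_id, strand, blocks, identity, score) {
  stopifnot(strand %in% c("+", "-"),
            all(c("q_start", "t_start", "length") %in% names(blocks)))
  blocks <- as.data.frame(blocks)[, c("q_start", "t_start", "length")]
  if (nrow(blocks) >= 1L) {
    if (any(blocks$length < 1L))
      stop("alignment block with length < 1")
    if (is.unsorted(blocks$q_start, strictly = TRUE) ||
        is.unsorted(blocks$t_start, strictly = TRUE))
      stop("alignment blocks are not co-linear")
    qe <- blocks$q_start + blocks$length
    te <- blocks$t_start + blocks$length
    n <- nrow(blocks)
    if (n > 1L && (any(blocks$q_start[-1L] < qe[-n]) ||
                   any(blocks$t_start[-1L] < te[-n])))
      stop("alignment blocks overlap")
  }
  structure(list(query_id = query_id, target_id = target_id, strand = strand,
                 blocks = blocks, identity = identity, score = as.integer(score)),
            class = "st_alignment")
}

#' @export
print.st_alignment <- function(x, ...) {
  cat("st_alignment ", x$query_id, " vs ", x$target_id, " (", x$strand,
      "): ", nrow(x$blocks), " block(s), score ", x$score,
      ", identity ", format(x$identity, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Construct a superTranscript
#'
#' The sorted linear sequence for one cluster plus, for every member
#' transcript, its ordered path of half-open intervals on that sequence.
#' Concatenating `substr(sequence, st_start+1, st_end)` over a transcript's
#' path reproduces the transcript sequence exactly (after any
#' strand normalisation applied during assembly).
#'
#' @param cluster_id cluster/gene id (used as the FASTA/GFF seqid).
#' @param sequence superTranscript DNA string.
#' @param paths named list (by transcript id) of data.frames with columns
#'   `st_start`, `st_end` (0-based half-open), strictly increasing.
#' @param used_transcripts,skipped_transcripts character vectors of ids.
#' @return An object of class `super_transcript`.
#' @export
super_transcript <- function(cluster_id, sequence, paths,
                             used_transcripts = names(paths),
                             skipped_transcripts = character()) {
  L <- nchar(sequence)
  for (tx in names(paths)) {
    p <- paths[[tx]]
    stopifnot(all(c("st_start", "st_end") %in% names(p)))
    if (nrow(p) == 0L) stop("empty path for transcript ", tx)
    if (any(p$st_start >= p$st_end) || any(p$st_start < 0L) || any(p$st_end > L))
      stop("invalid path interval for transcript ", tx)
    if (nrow(p) > 1L && any(p$st_start[-1L] < p$st_end[-nrow(p)]))
      stop("path intervals overlap for transcript ", tx)
  }
  structure(list(cluster_id = cluster_id, sequence = sequence,
                 paths = paths,
                 used_transcripts = used_transcripts,
                 skipped_transcripts = skipped_transcripts),
            class = "super_transcript")
}

#' @export
print.super_transcript <- function(x, ...) {
  cat("super_transcript '", x$cluster_id, "': ", nchar(x$sequence),
      " bp, ", length(x$used_transcripts), " transcript(s)",
      if (length(x$skipped_transcripts))
        paste0(", ", length(x$skipped_transcripts), " skipped"),
      "\n", sep = "")
  invisible(x)
}

#' Extract the sequence spelled by a transcript path
#'
#' @param st a `super_transcript`.
#' @param transcript_id transcript id present in `st$paths`.
#' @return The concatenation of the superTranscript substrings along the
#'   transcript's path.
#' @export
path_sequence <- function(st, transcript_id) {
  p <- st$paths[[transcript_id]]
  if (is.null(p)) stop("no path for transcript ", transcript_id)
  paste(substring(st$sequence, p$st_start + 1L, p$st_end), collapse = "")
}

# ---- small shared utilities -------------------------------------------------

normalize_dna <- function(seqs) {
  seqs <- chartr("u", "t", toupper(as.character(seqs)))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    warning(sum(bad), " sequence(s) contained non-ACGTN characters; replaced by N")
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  seqs
}

#' Reverse-complement a DNA string
#'
#' @param seq character vector of DNA strings over `A,C,G,T,N`.
#' @return Reverse complement(s).
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                   collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All fixture generators route through this so
# they are pure functions of their seed.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
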
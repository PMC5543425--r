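# Co-linear pairwise alignment of transcripts: internal exact-seed chain
# aligner plus a PSL import path for externally produced alignments.

# All maximal exact matches of length >= max(k, min_len) between a and b,
# found from shared k-mer seeds merged along diagonals.
maximal_exact_blocks <- function(a, b, k, min_len) {
  la <- nchar(a); lb <- nchar(b)
  if (la < k || lb < k) return(NULL)
  ka <- substring(a, seq_len(la - k + 1L), seq_len(la - k + 1L) + k - 1L)
  kb <- substring(b, seq_len(lb - k + 1L), seq_len(lb - k + 1L) + k - 1L)
  pos_b <- split(seq_along(kb), kb)
  hits <- pos_b[ka]
  nh <- lengths(hits)
  if (sum(nh) == 0L) return(NULL)
  qh <- rep.int(seq_along(ka), nh)
  th <- unlist(hits, use.names = FALSE)
  d <- qh - th
  o <- order(d, qh)
  qh <- qh[o]; th <- th[o]; d <- d[o]
  # runs of consecutive hits on one diagonal are one maximal exact match
  new_run <- c(TRUE, diff(qh) != 1L | diff(d) != 0L)
  run_id <- cumsum(new_run)
  q0 <- qh[new_run]
  t0 <- th[new_run]
  len <- tabulate(run_id) + k - 1L
  keep <- len >= max(k, min_len)
  if (!any(keep)) return(NULL)
  data.frame(q_start = q0[keep] - 1L, t_start = t0[keep] - 1L,
             length = len[keep])
}

# Highest-scoring co-linear chain of blocks (score = matched bases), by
# quadratic DP. Slightly overlapping blocks (a match extending a few bases
# past a junction can overlap the next exon's match) are admitted by
# trimming the later block's start on both coordinates; trimmed blocks must
# stay at least min_len long. Deterministic tie-breaks (first optimum in
# sorted order).
best_chain <- function(blocks, min_len = 1L) {
  if (is.null(blocks) || nrow(blocks) == 0L) return(NULL)
  o <- order(blocks$q_start, blocks$t_start)
  blocks <- blocks[o, , drop = FALSE]
  n <- nrow(blocks)
  qs <- blocks$q_start; ts <- blocks$t_start; len <- blocks$length
  qe <- qs + len; te <- ts + len
  score <- as.numeric(len)
  prev <- rep.int(0L, n)
  trim <- rep.int(0L, n)
  for (j in seq_len(n)) {
    if (j == 1L) next
    i <- seq_len(j - 1L)
    ov <- pmax(0L, pmax(qe[i] - qs[j], te[i] - ts[j]))
    ok <- qs[i] < qs[j] & ts[i] < ts[j] & (len[j] - ov) >= min_len
    if (any(ok)) {
      cand <- score[i] + len[j] - ov
      cand[!ok] <- -Inf
      b <- which.max(cand)
      if (cand[b] > score[j]) {
        score[j] <- cand[b]; prev[j] <- b; trim[j] <- ov[b]
      }
    }
  }
  j <- which.max(score)
  chain <- integer(); trims <- integer()
  while (j != 0L) { chain <- c(j, chain); trims <- c(trim[j], trims); j <- prev[j] }
  out <- blocks[chain, , drop = FALSE]
  out$q_start <- out$q_start + trims
  out$t_start <- out$t_start + trims
  out$length <- out$length - trims
  list(blocks = out, score = sum(out$length))
}

#' Align two sequences with the internal gapless chain aligner
#'
#' Seed-and-extend on exact k-mer seeds: maximal exact matches of length at
#' least `min_block_len` are collected and chained by co-linearity; the
#' highest-scoring chain (score = matched bases) is kept. Both orientations
#' are evaluated and the better-scoring strand returned; for strand `"-"`
#' block target coordinates refer to the reverse-complemented target frame.
#' Blocks are exact matches, so the identity of internally produced
#' alignments is 1. `min_block_len` and `k` are capped at the shorter
#' sequence length, so full-length identity between short sequences is
#' always found.
#'
#' @param seq_a,seq_b DNA strings (query, target).
#' @param min_block_len minimum length of a reported gapless block.
#' @param min_identity minimum overall identity (only filters imported
#'   alignments; internal blocks are exact).
#' @param k seed k-mer size.
#' @param query_id,target_id ids recorded in the returned alignment.
#' @return An [st_alignment], or `NULL` when no chain qualifies.
#' @export
align_pair <- function(seq_a, seq_b, min_block_len = 20L, min_identity = 0.98,
                       k = 11L, query_id = "query", target_id = "target") {
  stopifnot(nchar(seq_a) >= 1L, nchar(seq_b) >= 1L)
  mbl <- max(1L, min(as.integer(min_block_len), nchar(seq_a), nchar(seq_b)))
  keff <- max(1L, min(as.integer(k), mbl))
  fwd <- best_chain(maximal_exact_blocks(seq_a, seq_b, keff, mbl), mbl)
  rev <- best_chain(maximal_exact_blocks(seq_a, revcomp(seq_b), keff, mbl), mbl)
  if (is.null(fwd) && is.null(rev)) return(NULL)
  sf <- if (is.null(fwd)) -1 else fwd$score
  sr <- if (is.null(rev)) -1 else rev$score
  if (sf >= sr) {
    st_alignment(query_id, target_id, "+", fwd$blocks, 1.0, fwd$score)
  } else {
    st_alignment(query_id, target_id, "-", rev$blocks, 1.0, rev$score)
  }
}

# All disjoint local chains between a and b on one strand, greedily peeled
# in decreasing score order (mirrors an external local aligner reporting
# several hits per pair, which is what lets shared repeats merge and form
# cycles in the splice graph).
local_chains <- function(seq_a, seq_b, min_block_len, k) {
  blocks <- maximal_exact_blocks(seq_a, seq_b, k, min_block_len)
  out <- list()
  while (!is.null(blocks) && nrow(blocks) > 0L) {
    ch <- best_chain(blocks, min_block_len)
    if (is.null(ch) || ch$score < min_block_len) break
    out[[length(out) + 1L]] <- ch
    qs <- ch$blocks$q_start; qe <- qs + ch$blocks$length
    ts <- ch$blocks$t_start; te <- ts + ch$blocks$length
    keep <- rep(TRUE, nrow(blocks))
    for (i in seq_along(qs)) {
      keep <- keep & (blocks$q_start + blocks$length <= qs[i] |
                      blocks$q_start >= qe[i]) &
                     (blocks$t_start + blocks$length <= ts[i] |
                      blocks$t_start >= te[i])
    }
    # also drop blocks overlapping the used regions on either axis
    blocks <- blocks[keep, , drop = FALSE]
  }
  out
}

#' Compute all within-cluster pairwise alignments
#'
#' Alignments are computed for all unordered pairs among the first
#' `max_transcripts` transcripts by input rank (the default 50-transcript
#' cap); transcripts beyond the cap are recorded in the `skipped` attribute.
#' For each pair every disjoint local chain is reported (an external local
#' aligner would likewise emit several hits for e.g. a shared repeat), in
#' deterministic `(rank_i, rank_j)` order.
#'
#' @param cluster an [st_cluster].
#' @param max_transcripts cap on the number of transcripts used.
#' @param min_block_len,k see [align_pair()].
#' @return List of [st_alignment] (possibly several per pair), with
#'   attribute `skipped` holding ids of capped transcripts.
#' @export
cluster_alignments <- function(cluster, max_transcripts = 50L,
                               min_block_len = 20L, k = 11L) {
  stopifnot(inherits(cluster, "st_cluster"), length(cluster$ids) >= 1L)
  n_use <- min(length(cluster$ids), max_transcripts)
  skipped <- if (length(cluster$ids) > n_use)
    cluster$ids[(n_use + 1L):length(cluster$ids)] else character()
  out <- list()
  if (n_use >= 2L) {
    for (i in seq_len(n_use - 1L)) {
      for (j in (i + 1L):n_use) {
        a <- cluster$seqs[i]; b <- cluster$seqs[j]
        mbl <- max(1L, min(as.integer(min_block_len), nchar(a), nchar(b)))
        keff <- max(1L, min(as.integer(k), mbl))
        fwd <- local_chains(a, b, mbl, keff)
        rev <- local_chains(a, revcomp(b), mbl, keff)
        sf <- if (length(fwd)) fwd[[1L]]$score else -1
        sr <- if (length(rev)) rev[[1L]]$score else -1
        chains <- if (sf >= sr) fwd else rev
        strand <- if (sf >= sr) "+" else "-"
        for (ch in chains)
          out[[length(out) + 1L]] <- st_alignment(
            cluster$ids[i], cluster$ids[j], strand, ch$blocks, 1.0, ch$score)
      }
    }
  }
  attr(out, "skipped") <- skipped
  out
}

#' Strand-normalise a cluster using its pairwise alignments
#'
#' De novo contigs may be assembled in opposite orientations. Within each
#' connected component of the alignment graph, orientations are propagated
#' from the lowest-rank transcript: a transcript whose best alignment toward
#' the component anchor is on the `-` strand is reverse-complemented.
#' Transcripts with no alignment are left unchanged. Alignments must be
#' recomputed after flipping (see [assemble_cluster()]).
#'
#' @param cluster an [st_cluster].
#' @param alignments list of [st_alignment] from [cluster_alignments()].
#' @return The cluster with strand-normalised sequences; attribute `flipped`
#'   lists the ids that were reverse-complemented.
#' @export
orient_cluster <- function(cluster, alignments) {
  n <- length(cluster$ids)
  idx <- stats::setNames(seq_len(n), cluster$ids)
  # best alignment per unordered pair
  best <- list()
  for (al in alignments) {
    key <- paste(al$query_id, al$target_id, sep = "\r")
    if (is.null(best[[key]]) || al$score > best[[key]]$score) best[[key]] <- al
  }
  adj <- vector("list", n)
  sgn <- list()
  for (al in best) {
    i <- idx[[al$query_id]]; j <- idx[[al$target_id]]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    sgn[[paste(i, j)]] <- al$strand
    sgn[[paste(j, i)]] <- al$strand
  }
  flip <- rep(FALSE, n)
  seen <- rep(FALSE, n)
  for (root in seq_len(n)) {          # ranks ascend with index
    if (seen[root]) next
    seen[root] <- TRUE
    queue <- root
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      for (v in sort(unique(adj[[u]]))) {
        if (seen[v]) next
        seen[v] <- TRUE
        flip[v] <- xor(flip[u], sgn[[paste(u, v)]] == "-")
        queue <- c(queue, v)
      }
    }
  }
  out <- cluster
  out$seqs[flip] <- revcomp(out$seqs[flip])
  attr(out, "flipped") <- cluster$ids[flip]
  out
}

#' Read BLAT PSL alignments
#'
#' Parses 21-column PSL (with or without the 5-line `psLayout` header) into
#' [st_alignment] records. Block lists come from `qStarts`/`tStarts`/
#' `blockSizes`; for `-` strand records the query coordinates (given by PSL
#' in the reversed-query frame) are converted to the forward query frame via
#' `qSize - qEnd`, and target coordinates to the reverse-complemented target
#' frame, so blocks increase in both coordinates. Identity is
#' `matches / (matches + misMatches)`.
#'
#' @param psl_path path to the PSL file.
#' @param id_filter optional character vector; only records whose query AND
#'   target ids are in the set are returned.
#' @return List of [st_alignment].
#' @export
read_psl <- function(psl_path, id_filter = NULL) {
  lines <- readLines(psl_path)
  out <- list()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) next
    if (grepl("^(psLayout|match\\s|\\s*match|-+$)", line) &&
        length(strsplit(line, "\t", fixed = TRUE)[[1]]) < 21L) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 21L)
      stop("malformed PSL line ", ln, ": expected 21 columns, got ", length(f))
    matches <- as.integer(f[1]); mismatches <- as.integer(f[2])
    strand <- substr(f[9], 1L, 1L)
    q_id <- f[10]; q_size <- as.integer(f[11])
    t_id <- f[14]; t_size <- as.integer(f[15])
    sizes <- as.integer(strsplit(f[19], ",", fixed = TRUE)[[1]])
    qst <- as.integer(strsplit(f[20], ",", fixed = TRUE)[[1]])
    tst <- as.integer(strsplit(f[21], ",", fixed = TRUE)[[1]])
    if (!is.null(id_filter) && !(q_id %in% id_filter && t_id %in% id_filter))
      next
    if (strand == "-") {
      # PSL gives qStarts on the reversed query; move q to the forward frame
      # and t to the revcomp target frame so both ascend.
      qst <- q_size - (qst + sizes)
      tst <- t_size - (tst + sizes)
      o <- order(qst)
      qst <- qst[o]; tst <- tst[o]; sizes <- sizes[o]
    }
    identity <- if (matches + mismatches > 0)
      matches / (matches + mismatches) else 0
    out[[length(out) + 1L]] <- st_alignment(
      q_id, t_id, strand,
      data.frame(q_start = qst, t_start = tst, length = sizes),
      identity, matches)
  }
  out
}
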
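# Block annotation: counting bins on a superTranscript, either from the
# graph/path structure (standard) or from spliced read junctions (dynamic).

blocks_from_boundaries <- function(bnd, L, kind) {
  bnd <- sort(unique(c(0L, L, bnd)))
  bnd <- bnd[bnd >= 0L & bnd <= L]
  data.frame(st_start = bnd[-length(bnd)], st_end = bnd[-1L], kind = kind)
}

#' Standard blocks from transcript paths
#'
#' Block boundaries are the forks and divergences of the splice graph, which
#' after serialisation are exactly the endpoints of the transcript path
#' intervals: the boundary set is `{0, L}` plus every `st_start` and
#' `st_end` of every path interval. Adjacent exons that are always spliced
#' together therefore collapse into a single block.
#'
#' @param st a [super_transcript].
#' @return data.frame of blocks (`st_start`, `st_end`, `kind = "standard"`)
#'   partitioning `[0, L)`.
#' @export
standard_blocks <- function(st) {
  L <- nchar(st$sequence)
  ends <- unlist(lapply(st$paths, function(p) c(p$st_start, p$st_end)),
                 use.names = FALSE)
  blocks_from_boundaries(ends, L, "standard")
}

#' Extract splice junctions from read alignments
#'
#' Every `N` operation in a CIGAR yields one junction: `left` is the
#' 0-based reference position where the skip begins, `right = left + skip`.
#' Junctions whose flanking aligned (`M`/`=`/`X`) run is shorter than
#' `min_overhang` on either side are ignored, as are unmapped, secondary
#' and supplementary records. Support counts each alignment record's N
#' operations individually.
#'
#' @param path SAM or BAM file of reads aligned to superTranscripts (SAM is
#'   converted on the fly).
#' @param min_overhang minimum flanking matched segment (default 12,
#'   mirroring common splice-junction overhang filters).
#' @return data.frame with columns `st_id`, `left`, `right`, `support`,
#'   sorted by `(st_id, left, right)`.
#' @export
extract_junctions <- function(path, min_overhang = 12L) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  rec <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    flag = flags, what = c("rname", "pos", "cigar")))[[1]]
  n <- length(rec$pos)
  out <- list()
  if (n) {
    ops <- GenomicAlignments::explodeCigarOps(rec$cigar)
    lens <- GenomicAlignments::explodeCigarOpLengths(rec$cigar)
    for (i in seq_len(n)) {
      op <- ops[[i]]; ln <- lens[[i]]
      if (!any(op == "N")) next
      ref_consume <- op %in% c("M", "=", "X", "D", "N")
      ref_off <- cumsum(c(0L, ln * ref_consume))[seq_along(op)]
      ref_len <- unname(hdr[as.character(rec$rname[i])])
      end_ref <- (rec$pos[i] - 1L) + ref_off[length(op)] +
        ln[length(op)] * ref_consume[length(op)]
      if (!is.na(ref_len) && end_ref > ref_len) {
        warning("alignment record ", i, " extends beyond reference ",
                rec$rname[i], "; skipped")
        next
      }
      # aligned-run length adjacent to each op (M/=/X only)
      match_run <- ifelse(op %in% c("M", "=", "X"), ln, 0L)
      for (j in which(op == "N")) {
        lf <- if (j > 1L) match_run[j - 1L] else 0L
        rf <- if (j < length(op)) match_run[j + 1L] else 0L
        if (lf < min_overhang || rf < min_overhang) next
        left <- (rec$pos[i] - 1L) + ref_off[j]
        out[[length(out) + 1L]] <- data.frame(
          st_id = as.character(rec$rname[i]),
          left = left, right = left + ln[j])
      }
    }
  }
  if (!length(out))
    return(data.frame(st_id = character(), left = integer(),
                      right = integer(), support = integer()))
  j <- do.call(rbind, out)
  agg <- stats::aggregate(list(support = rep.int(1L, nrow(j))),
                          by = j[c("st_id", "left", "right")], FUN = sum)
  agg[order(agg$st_id, agg$left, agg$right), , drop = FALSE]
}

#' Dynamic blocks from junction support
#'
#' Boundary set: `{0, L}` plus `left` and `right` of every junction
#' supported by at least `min_support` reads (default 5 spliced reads).
#'
#' @param st a [super_transcript] (or a single sequence length via
#'   `st_length`).
#' @param junctions data.frame as returned by [extract_junctions()]
#'   (rows for other superTranscripts are ignored).
#' @param min_support minimum read support for a junction boundary.
#' @param st_length optional length override when `st` is missing.
#' @return data.frame of blocks (`kind = "dynamic"`) partitioning `[0, L)`.
#' @export
dynamic_blocks <- function(st, junctions, min_support = 5L, st_length = NULL) {
  L <- if (is.null(st_length)) nchar(st$sequence) else st_length
  j <- junctions
  if (nrow(j) && "st_id" %in% names(j) && !is.null(st$cluster_id))
    j <- j[j$st_id == st$cluster_id, , drop = FALSE]
  if (nrow(j) && (any(j$left < 0L) || any(j$right > L)))
    stop("junction coordinates outside [0, L]")
  j <- j[j$support >= min_support, , drop = FALSE]
  blocks_from_boundaries(c(j$left, j$right), L, "dynamic")
}

#' Annotate a superTranscript with blocks
#'
#' Thin composition: computes (or accepts) the block partition for the
#' requested mode and returns the GFF-ready feature set; writing goes
#' through [write_supertranscriptome()].
#'
#' @param st a [super_transcript].
#' @param mode `"standard"` (graph/path derived) or `"dynamic"`
#'   (read derived; requires `junctions`).
#' @param junctions junction table for dynamic mode.
#' @param min_support dynamic-mode support threshold.
#' @return List with `blocks` (data.frame) and `features` (GRanges as
#'   emitted to GFF3).
#' @export
annotate <- function(st, mode = c("standard", "dynamic"),
                     junctions = NULL, min_support = 5L) {
  mode <- match.arg(mode)
  blocks <- if (mode == "standard") {
    standard_blocks(st)
  } else {
    if (is.null(junctions)) stop("dynamic mode requires a junction table")
    dynamic_blocks(st, junctions, min_support = min_support)
  }
  list(blocks = blocks, features = st_features(st, blocks))
}
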
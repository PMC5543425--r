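# Genome-based superTranscripts: flatten each gene's exons into disjoint
# genomic intervals, concatenate their sequence (reverse-complemented for
# minus-strand genes so the superTranscript reads 5'->3'), project transcript
# coordinates, and lift superTranscript positions back through UCSC chains.

#' Flatten a gene's exons into disjoint intervals
#'
#' @param exons data.frame with columns `start`, `end` (0-based half-open)
#'   and optionally `chrom`, `strand` (must be uniform within the gene).
#' @param gene_id used in error messages.
#' @return An object of class `st_flat_gene`: `gene_id`, `chrom`, `strand`,
#'   `exon_union` (data.frame `start`,`end`, sorted, disjoint, non-adjacent)
#'   and `st_length`.
#' @export
flatten_gene <- function(exons, gene_id = "gene") {
  chrom <- if ("chrom" %in% names(exons)) unique(exons$chrom) else "chr"
  strand <- if ("strand" %in% names(exons)) unique(exons$strand) else "+"
  if (length(chrom) != 1L || length(strand) != 1L)
    stop("mixed chromosome/strand within gene '", gene_id, "'")
  ir <- IRanges::reduce(IRanges::IRanges(exons$start + 1L, exons$end))
  union <- data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exon_union = union,
                 st_length = sum(union$end - union$start)),
            class = "st_flat_gene")
}

# genomic position -> concatenated (plus-frame) superTranscript coordinate
# helpers for one flattened gene
flat_offsets <- function(flat) {
  lens <- flat$exon_union$end - flat$exon_union$start
  c(0L, cumsum(lens))[seq_along(lens)]
}

#' Project transcript exon structures onto a flattened gene
#'
#' Each transcript exon (which must be contained in one union interval) is
#' mapped through the genomic-to-superTranscript coordinate function;
#' adjacent mapped intervals are merged. For minus-strand genes the
#' superTranscript is the reverse complement of the concatenation, so
#' intervals are flipped into the final frame and emitted in 5'->3'
#' superTranscript order.
#'
#' @param flat an `st_flat_gene`.
#' @param tx_exons named list (by transcript id) of data.frames with
#'   `start`, `end` (0-based half-open genomic).
#' @return Named list of path data.frames (`st_start`, `st_end`).
#' @export
project_transcripts <- function(flat, tx_exons) {
  u <- flat$exon_union
  offs <- flat_offsets(flat)
  L <- flat$st_length
  lapply(tx_exons, function(ex) {
    ex <- ex[order(ex$start), , drop = FALSE]
    iv <- match_interval(ex, u)
    if (anyNA(iv))
      stop("exon not contained in the flattened union of gene '",
           flat$gene_id, "'")
    s <- offs[iv] + (ex$start - u$start[iv])
    e <- s + (ex$end - ex$start)
    if (flat$strand == "-") {
      tmp <- L - e; e <- L - s; s <- tmp
      o <- order(s); s <- s[o]; e <- e[o]
    }
    keep <- c(TRUE, s[-1L] != e[-length(e)])
    grp <- cumsum(keep)
    data.frame(st_start = as.integer(tapply(s, grp, min)),
               st_end = as.integer(tapply(e, grp, max)))
  })
}

match_interval <- function(ex, u) {
  vapply(seq_len(nrow(ex)), function(i) {
    j <- which(u$start <= ex$start[i] & ex$end[i] <= u$end)
    if (length(j) == 1L) j else NA_integer_
  }, integer(1))
}

#' Build a superTranscriptome from a genome and annotation
#'
#' Flattens each gene's exons into disjoint intervals, extracts and
#' concatenates their sequence (reverse complement for minus-strand genes),
#' maps the union intervals to superTranscript blocks, projects every
#' transcript, and emits one ungapped chain segment per union interval.
#'
#' @param genome_fasta path to the genome FASTA.
#' @param annotation_path GTF/GFF with exon features carrying `gene_id` and
#'   `transcript_id` attributes.
#' @return List with `sts` (named list of [super_transcript]), `blocks`
#'   (named list of block data.frames) and `chains` (named list of
#'   `st_chain`), genes in lexicographic order.
#' @export
build_genome_st <- function(genome_fasta, annotation_path) {
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  ann <- rtracklayer::import(annotation_path)
  ann <- ann[ann$type == "exon"]
  if (!all(c("gene_id", "transcript_id") %in% names(S4Vectors::mcols(ann))))
    stop("annotation exons must carry gene_id and transcript_id attributes")
  genes <- sort(unique(as.character(ann$gene_id)))
  sts <- list(); blocks <- list(); chains <- list()
  for (gid in genes) {
    ex <- ann[as.character(ann$gene_id) == gid]
    exdf <- data.frame(chrom = as.character(GenomicRanges::seqnames(ex)),
                       start = GenomicRanges::start(ex) - 1L,
                       end = GenomicRanges::end(ex),
                       strand = as.character(GenomicRanges::strand(ex)),
                       tx = as.character(ex$transcript_id))
    flat <- flatten_gene(exdf, gene_id = gid)
    if (!flat$chrom %in% names(genome))
      stop("chromosome '", flat$chrom, "' absent from genome FASTA")
    chrom_seq <- genome[[flat$chrom]]
    if (max(flat$exon_union$end) > length(chrom_seq))
      stop("exon exceeding chromosome length in gene '", gid, "'")
    pieces <- as.character(Biostrings::DNAStringSet(
      chrom_seq, start = flat$exon_union$start + 1L, end = flat$exon_union$end))
    seq <- paste(pieces, collapse = "")
    if (flat$strand == "-")
      seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq)))
    # union intervals as superTranscript blocks
    offs <- flat_offsets(flat)
    lens <- flat$exon_union$end - flat$exon_union$start
    bs <- offs; be <- offs + lens
    if (flat$strand == "-") {
      L <- flat$st_length
      tmp <- L - be; be <- L - bs; bs <- tmp
      o <- order(bs); bs <- bs[o]; be <- be[o]
    }
    tx_exons <- lapply(split(seq_len(nrow(exdf)), exdf$tx), function(i)
      exdf[i, c("start", "end"), drop = FALSE])
    paths <- project_transcripts(flat, tx_exons)
    sts[[gid]] <- super_transcript(gid, seq, paths)
    blocks[[gid]] <- data.frame(st_start = as.integer(bs),
                                st_end = as.integer(be), kind = "standard")
    chains[[gid]] <- chain_from_flat(flat, chrom_size = length(chrom_seq))
  }
  list(sts = sts, blocks = blocks, chains = chains)
}

#' Construct a chain record from a flattened gene
#'
#' One ungapped segment per union interval, in superTranscript order.
#'
#' @param flat an `st_flat_gene`.
#' @param chrom_size chromosome length (required for minus-strand chains).
#' @return An object of class `st_chain`: `st_id`, `st_size`, `chrom`,
#'   `chrom_size`, `strand` and `segments` (data.frame `st_start`, `len`,
#'   `g_start`, plus-frame genomic start of the segment).
#' @export
chain_from_flat <- function(flat, chrom_size) {
  u <- flat$exon_union
  offs <- flat_offsets(flat)
  lens <- u$end - u$start
  L <- flat$st_length
  if (flat$strand == "+") {
    seg <- data.frame(st_start = offs, len = lens, g_start = u$start)
  } else {
    st_start <- L - (offs + lens)
    seg <- data.frame(st_start = st_start, len = lens, g_start = u$start)
    seg <- seg[order(seg$st_start), , drop = FALSE]
  }
  structure(list(st_id = flat$gene_id, st_size = L, chrom = flat$chrom,
                 chrom_size = chrom_size, strand = flat$strand,
                 segments = seg),
            class = "st_chain")
}

#' Lift a superTranscript position to the genome
#'
#' Maps a 0-based superTranscript position through the containing ungapped
#' chain segment. Positions falling in no segment (possible for de novo
#' superTranscripts with genome-absent novel sequence) return an unmapped
#' result rather than an error.
#'
#' @param chain an `st_chain`.
#' @param st_position integer vector of 0-based positions in
#'   `[0, st_size)`.
#' @return data.frame with `chrom`, `genome_position` (0-based; `NA` when
#'   unmapped), `strand` and `mapped`.
#' @export
lift <- function(chain, st_position) {
  stopifnot(all(st_position >= 0L), all(st_position < chain$st_size))
  seg <- chain$segments
  gpos <- rep.int(NA_integer_, length(st_position))
  for (i in seq_len(nrow(seg))) {
    inside <- st_position >= seg$st_start[i] &
      st_position < seg$st_start[i] + seg$len[i]
    if (!any(inside)) next
    d <- st_position[inside] - seg$st_start[i]
    gpos[inside] <- if (chain$strand == "+") {
      seg$g_start[i] + d
    } else {
      seg$g_start[i] + seg$len[i] - 1L - d
    }
  }
  data.frame(chrom = chain$chrom, genome_position = gpos,
             strand = chain$strand, mapped = !is.na(gpos))
}

#' Lift a genomic position back to the superTranscript
#'
#' Inverse of [lift()] on the chain's segments; positions outside every
#' segment are unmapped.
#'
#' @param chain an `st_chain`.
#' @param genome_position 0-based genomic position vector.
#' @return Integer vector of superTranscript positions (`NA` = unmapped).
#' @export
lift_inverse <- function(chain, genome_position) {
  seg <- chain$segments
  stp <- rep.int(NA_integer_, length(genome_position))
  for (i in seq_len(nrow(seg))) {
    inside <- genome_position >= seg$g_start[i] &
      genome_position < seg$g_start[i] + seg$len[i]
    if (!any(inside)) next
    d <- genome_position[inside] - seg$g_start[i]
    stp[inside] <- if (chain$strand == "+") {
      seg$st_start[i] + d
    } else {
      seg$st_start[i] + seg$len[i] - 1L - d
    }
  }
  stp
}

#' Write chains as a UCSC chain file
#'
#' Target coordinates are the superTranscript (always `+`), query
#' coordinates the genome; minus-strand chains use the reversed-query frame
#' as the chain format specifies.
#'
#' @param chains list of `st_chain`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_chain <- function(chains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  id <- 0L
  for (ch in chains) {
    seg <- ch$segments
    if (nrow(seg) == 0L) next
    id <- id + 1L
    score <- sum(seg$len)
    t_start <- seg$st_start[1L]
    t_end <- seg$st_start[nrow(seg)] + seg$len[nrow(seg)]
    if (ch$strand == "+") {
      q <- seg$g_start
    } else {
      # reversed-strand frame: qPos = chrom_size - plus_end
      q <- ch$chrom_size - (seg$g_start + seg$len)
    }
    q_start <- q[1L]; q_end <- q[nrow(seg)] + seg$len[nrow(seg)]
    writeLines(sprintf("chain %d %s %d + %d %d %s %d %s %d %d %d",
                       score, ch$st_id, ch$st_size, t_start, t_end,
                       ch$chrom, ch$chrom_size, ch$strand,
                       q_start, q_end, id), con)
    n <- nrow(seg)
    if (n > 1L) {
      dt <- seg$st_start[-1L] - (seg$st_start[-n] + seg$len[-n])
      dq <- q[-1L] - (q[-n] + seg$len[-n])
      writeLines(sprintf("%d\t%d\t%d", seg$len[-n], dt, dq), con)
    }
    writeLines(c(sprintf("%d", seg$len[n]), ""), con)
  }
  invisible(path)
}

#' Read a UCSC chain file
#'
#' Parses chain records written by [write_chain()] (target =
#' superTranscript, query = genome) back into `st_chain` objects.
#'
#' @param path chain file.
#' @return Named list of `st_chain` (by superTranscript id).
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) { i <- i + 1L; next }
    f <- strsplit(line, "\\s+")[[1]]
    if (f[1] != "chain" || length(f) < 12L)
      stop("malformed chain header at line ", i)
    st_id <- f[3]; st_size <- as.integer(f[4])
    t_start <- as.integer(f[6])
    chrom <- f[8]; chrom_size <- as.integer(f[9]); strand <- f[10]
    q_start <- as.integer(f[11])
    seg <- list(); tpos <- t_start; qpos <- q_start
    i <- i + 1L
    repeat {
      if (i > length(lines)) stop("truncated chain record for ", st_id)
      df <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      sz <- as.integer(df[1])
      g_start <- if (strand == "+") qpos else chrom_size - (qpos + sz)
      seg[[length(seg) + 1L]] <- data.frame(st_start = tpos, len = sz,
                                            g_start = g_start)
      i <- i + 1L
      if (length(df) == 1L) break
      tpos <- tpos + sz + as.integer(df[2])
      qpos <- qpos + sz + as.integer(df[3])
    }
    out[[st_id]] <- structure(
      list(st_id = st_id, st_size = st_size, chrom = chrom,
           chrom_size = chrom_size, strand = strand,
           segments = do.call(rbind, seg)),
      class = "st_chain")
  }
  out
}

#' Build a chain from a superTranscript-vs-genome alignment
#'
#' Selects the best-scoring alignment after excluding targets matching the
#' exclusion pattern (alternative chromosomes, default suffix `_alt`); its
#' gapless blocks become the chain segments. Returns `NULL` (unmapped) when
#' no alignment qualifies.
#'
#' @param st_id superTranscript id.
#' @param st_size superTranscript length.
#' @param alignments list of [st_alignment] with the superTranscript as
#'   query and chromosomes as targets.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param exclude_pattern regular expression for excluded target names.
#' @param min_score minimum alignment score.
#' @return An `st_chain`, or `NULL` when the superTranscript is unmapped.
#' @export
chain_from_alignment <- function(st_id, st_size, alignments, chrom_sizes,
                                 exclude_pattern = "_alt$", min_score = 0L) {
  alns <- Filter(function(a) a$query_id == st_id &&
                   !grepl(exclude_pattern, a$target_id) &&
                   a$score >= min_score, alignments)
  if (!length(alns)) return(NULL)
  best <- alns[[which.max(vapply(alns, `[[`, integer(1), "score"))]]
  chrom_size <- unname(chrom_sizes[best$target_id])
  b <- best$blocks
  if (best$strand == "+") {
    seg <- data.frame(st_start = b$q_start, len = b$length, g_start = b$t_start)
  } else {
    # t coords are in the revcomp target frame; back to plus frame
    seg <- data.frame(st_start = b$q_start, len = b$length,
                      g_start = chrom_size - (b$t_start + b$length))
  }
  structure(list(st_id = st_id, st_size = st_size, chrom = best$target_id,
                 chrom_size = chrom_size, strand = best$strand,
                 segments = seg),
            class = "st_chain")
}

#' @export
print.st_chain <- function(x, ...) {
  cat("st_chain ", x$st_id, " -> ", x$chrom, " (", x$strand, "): ",
      nrow(x$segments), " segment(s), ", sum(x$segments$len),
      " aligned base(s)\n", sep = "")
  invisible(x)
}
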
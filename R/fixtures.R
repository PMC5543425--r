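# Seeded synthetic-data generators: gene models with planted exons, isoform
# sets, spliced reads over a superTranscript, and the shared-repeat cluster
# that forces a cycle in the splice graph. All are pure functions of their
# seed, and every truth object is sufficient to compute expected outputs
# (union lengths, block boundaries, junction counts) without running the
# assembler.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a gene: genome segment with planted exons
#'
#' Random DNA with `n_exons` exons separated by introns; lengths drawn
#' uniformly from the given ranges. Defaults (exons 50-300 bp) mimic
#' compact vertebrate genes while staying small enough for exhaustive
#' oracles.
#'
#' For genes with up to five exons, junction guard bases are planted: every
#' exon that can follow a junction gets a distinct first base and every exon
#' that can precede one a distinct last base. This ensures exact alignments
#' between isoforms stop exactly at exon boundaries, so the exon-union
#' length is by construction the exact non-redundant superTranscript length
#' (the truth objects fully determine the expected output). With more than
#' five exons the four-letter alphabet cannot guarantee this and truth union
#' lengths may differ from sequence-level non-redundancy by a few bases.
#'
#' @param n_exons number of exons (>= 1).
#' @param exon_len_range,intron_len_range inclusive length ranges.
#' @param seed RNG seed; the generator is deterministic under it.
#' @param chrom,strand placed chromosome name and gene strand.
#' @return List with `chrom`, `strand`, `genome_seq`, `exons` (data.frame
#'   `start`,`end`, 0-based half-open) and `union_length`.
#' @export
simulate_gene <- function(n_exons, exon_len_range = c(50L, 300L),
                          intron_len_range = c(20L, 100L), seed = 1L,
                          chrom = "chrS", strand = "+") {
  stopifnot(n_exons >= 1L, all(exon_len_range >= 1L),
            all(intron_len_range >= 1L))
  with_seed(seed, {
    exon_len <- sample(exon_len_range[1]:exon_len_range[2], n_exons,
                       replace = TRUE)
    intron_len <- if (n_exons > 1L)
      sample(intron_len_range[1]:intron_len_range[2], n_exons - 1L,
             replace = TRUE) else integer()
    lead <- sample(10:50, 1L)
    starts <- lead + c(0L, cumsum(exon_len[-n_exons] + intron_len))
    ends <- starts + exon_len
    total <- ends[n_exons] + sample(10:50, 1L)
    seq <- random_dna(total)
    if (n_exons >= 2L && n_exons <= 5L && all(exon_len >= 2L)) {
      chars <- strsplit(seq, "", fixed = TRUE)[[1]]
      letters4 <- c("A", "C", "G", "T")
      for (i in 2:n_exons)                  # distinct junction-entry bases
        chars[starts[i] + 1L] <- letters4[i - 1L]
      for (i in 1:(n_exons - 1L))           # distinct junction-exit bases
        chars[ends[i]] <- letters4[i]
      seq <- paste(chars, collapse = "")
    }
    list(chrom = chrom, strand = strand,
         genome_seq = seq,
         exons = data.frame(start = starts, end = ends),
         union_length = sum(exon_len))
  })
}

exon_seq <- function(gene, i) {
  substring(gene$genome_seq, gene$exons$start[i] + 1L, gene$exons$end[i])
}

#' Simulate isoforms as exon subsets of a gene
#'
#' Each isoform keeps a random subset of exons (first and last always kept;
#' every exon is kept by at least one isoform so the exon union is
#' recoverable from the transcripts alone) and its sequence is the
#' concatenation of the kept exon sequences. Truth includes every isoform's
#' interval chain on the exon-union superTranscript (the concatenation of
#' all exons in genomic order).
#'
#' @param gene result of [simulate_gene()].
#' @param n_isoforms number of isoforms (>= 1).
#' @param keep_prob probability of keeping each interior exon.
#' @param seed RNG seed.
#' @param cluster_id cluster name for the returned [st_cluster].
#' @return List with `cluster` ([st_cluster]), `kept` (list of kept exon
#'   index vectors), `truth_paths` (list of data.frames `st_start`,`st_end`
#'   on the exon-union superTranscript), `union_sequence` and
#'   `union_length`.
#' @export
simulate_isoforms <- function(gene, n_isoforms, keep_prob = 0.8, seed = 1L,
                              cluster_id = "gene1") {
  stopifnot(n_isoforms >= 1L)
  n_ex <- nrow(gene$exons)
  with_seed(seed, {
    kept <- lapply(seq_len(n_isoforms), function(i) {
      keep <- stats::runif(n_ex) < keep_prob
      keep[c(1L, n_ex)] <- TRUE
      which(keep)
    })
    miss <- setdiff(seq_len(n_ex), unique(unlist(kept)))
    for (m in seq_along(miss)) {            # every exon kept by >= 1 isoform
      i <- ((m - 1L) %% n_isoforms) + 1L
      kept[[i]] <- sort(unique(c(kept[[i]], miss[m])))
    }
    exlens <- gene$exons$end - gene$exons$start
    offs <- c(0L, cumsum(exlens))
    seqs <- vapply(kept, function(ix)
      paste(vapply(ix, function(i) exon_seq(gene, i), character(1)),
            collapse = ""), character(1))
    truth <- lapply(kept, function(ix) {
      s <- offs[ix]; e <- offs[ix] + exlens[ix]
      keep_start <- c(TRUE, s[-1L] != e[-length(e)])
      grp <- cumsum(keep_start)
      data.frame(st_start = as.integer(tapply(s, grp, min)),
                 st_end = as.integer(tapply(e, grp, max)))
    })
    ids <- sprintf("%s.iso%d", cluster_id, seq_len(n_isoforms))
    union_seq <- paste(vapply(seq_len(n_ex), function(i) exon_seq(gene, i),
                              character(1)), collapse = "")
    list(cluster = st_cluster(cluster_id, ids, seqs),
         kept = kept,
         truth_paths = stats::setNames(truth, ids),
         union_sequence = union_seq,
         union_length = sum(exlens))
  })
}

#' Simulate spliced reads over a superTranscript as SAM records
#'
#' For every junction implied by the truth paths (a gap between consecutive
#' path intervals of an isoform), emits exactly `per_junction_support`
#' spliced reads whose CIGAR contains an `N` operation spanning the skipped
#' region, flanked by `overhang` matched bases on each side, plus a few
#' unspliced reads. The header declares the superTranscript length.
#'
#' @param st_id,st_length reference name and length declared in the header.
#' @param truth_paths list of path data.frames defining the junctions.
#' @param per_junction_support reads emitted per junction.
#' @param overhang matched bases flanking the junction on each side.
#' @param seed RNG seed (ordering only; coordinates are deterministic).
#' @param path optional output file; when `NULL` the SAM text is returned.
#' @return Character vector of SAM lines (invisibly when written to
#'   `path`), with attribute `junctions` (data.frame `left`, `right`).
#' @export
simulate_spliced_reads <- function(st_id, st_length, truth_paths,
                                   per_junction_support = 5L, overhang = 20L,
                                   seed = 1L, path = NULL) {
  juncs <- unique(do.call(rbind, lapply(truth_paths, function(p) {
    n <- nrow(p)
    if (n < 2L) return(NULL)
    data.frame(left = p$st_end[-n], right = p$st_start[-1L])
  })))
  if (is.null(juncs)) juncs <- data.frame(left = integer(), right = integer())
  juncs <- juncs[juncs$right > juncs$left, , drop = FALSE]
  lines <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", st_id, st_length))
  rid <- 0L
  with_seed(seed, {
    if (nrow(juncs)) {
      for (i in seq_len(nrow(juncs))) {
        left <- juncs$left[i]; right <- juncs$right[i]
        if (left - overhang < 0L || right + overhang > st_length) next
        for (r in seq_len(per_junction_support)) {
          rid <- rid + 1L
          pos <- left - overhang                       # 0-based start
          cigar <- sprintf("%dM%dN%dM", overhang, right - left, overhang)
          seqlen <- 2L * overhang
          lines <- c(lines, sprintf(
            "r%04d\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
            rid, st_id, pos + 1L, cigar,
            paste(rep.int("A", seqlen), collapse = "")))
        }
      }
    }
    for (r in seq_len(3L)) {                           # unspliced filler
      rid <- rid + 1L
      pos <- sample.int(max(1L, st_length - 40L), 1L) - 1L
      lines <- c(lines, sprintf(
        "r%04d\t0\t%s\t%d\t60\t40M\t*\t0\t0\t%s\t*",
        rid, st_id, pos + 1L, paste(rep.int("A", 40L), collapse = "")))
    }
  })
  attr(lines, "junctions") <- juncs
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Shared-repeat cluster inducing a splice-graph cycle
#'
#' Two transcripts sharing two units in opposite order
#' (`GGGAAACCC` / `CCCAAATTT` for `unit_len = 3`): merging both shared
#' units (`AAA` and `CCC`) creates the cycle `AAA -> CCC -> AAA`, whose
#' minimal node is duplicated during cycle breaking, giving the 15-base
#' superTranscript `GGGAAACCCAAATTT`. The unit letters are chosen so that
#' neither transcript's reverse complement aligns to the other better than
#' its forward orientation (strand normalisation must not fire). Assemble
#' with `min_block_len = unit_len, k = unit_len`.
#'
#' @param unit_len length of each homopolymer unit.
#' @param cluster_id cluster name.
#' @return An [st_cluster] with attribute `expected_sequence` (the
#'   15-base-family outcome `G..A..C..A..T..`) and `unit_len`.
#' @export
repeat_fixture <- function(unit_len = 3L, cluster_id = "repeat1") {
  u <- function(ch) paste(rep.int(ch, unit_len), collapse = "")
  cl <- st_cluster(cluster_id,
                   c("t1", "t2"),
                   c(paste0(u("G"), u("A"), u("C")),
                     paste0(u("C"), u("A"), u("T"))))
  attr(cl, "expected_sequence") <-
    paste0(u("G"), u("A"), u("C"), u("A"), u("T"))
  attr(cl, "unit_len") <- unit_len
  cl
}

#' Write a fixture preset to disk
#'
#' Presets: `basic` (one multi-isoform gene; FASTA + cluster TSV), `cycle`
#' (the shared-repeat cluster), `junction` (superTranscript FASTA + spliced
#' SAM), `genome` (genome FASTA + GTF annotation).
#'
#' @param preset one of `"basic"`, `"cycle"`, `"junction"`, `"genome"`.
#' @param seed RNG seed.
#' @param dir output directory (created if needed).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_fixture <- function(preset = c("basic", "cycle", "junction", "genome"),
                          seed = 1L, dir) {
  preset <- match.arg(preset)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cluster_files <- function(cluster, stem) {
    fa <- file.path(dir, paste0(stem, ".fasta"))
    tsv <- file.path(dir, paste0(stem, "_clusters.txt"))
    dna <- Biostrings::DNAStringSet(cluster$seqs)
    names(dna) <- cluster$ids
    Biostrings::writeXStringSet(dna, fa)
    writeLines(paste(cluster$ids, cluster$cluster_id, sep = "\t"), tsv)
    c(fasta = fa, clusters = tsv)
  }
  files <- switch(preset,
    basic = {
      gene <- simulate_gene(5L, seed = seed)
      iso <- simulate_isoforms(gene, 3L, seed = seed + 1L)
      write_cluster_files(iso$cluster, "transcripts")
    },
    cycle = write_cluster_files(repeat_fixture(), "repeat"),
    junction = {
      gene <- simulate_gene(3L, seed = seed)
      iso <- simulate_isoforms(gene, 2L, keep_prob = 0.5, seed = seed + 1L)
      fa <- file.path(dir, "superTranscript.fasta")
      dna <- Biostrings::DNAStringSet(iso$union_sequence)
      names(dna) <- "gene1"
      Biostrings::writeXStringSet(dna, fa)
      sam <- file.path(dir, "reads.sam")
      simulate_spliced_reads("gene1", iso$union_length, iso$truth_paths,
                             seed = seed, path = sam)
      c(fasta = fa, sam = sam)
    },
    genome = {
      gm <- simulate_genome_annotation(n_genes = 3L, seed = seed)
      fa <- file.path(dir, "genome.fasta")
      gtf <- file.path(dir, "annotation.gtf")
      Biostrings::writeXStringSet(gm$genome, fa)
      rtracklayer::export(gm$annotation, gtf, format = "gtf")
      c(genome = fa, annotation = gtf)
    })
  invisible(files)
}

#' Simulate a multi-gene genome with GTF-style annotation
#'
#' Places one gene per chromosome (alternating strand), each with 2-5 exons
#' and 1-3 isoforms, and returns the genome as a `DNAStringSet` plus exon
#' annotation as a `GRanges` carrying `gene_id`/`transcript_id`, ready for
#' [build_genome_st()].
#'
#' @param n_genes number of genes.
#' @param seed RNG seed.
#' @return List with `genome` (DNAStringSet), `annotation` (GRanges),
#'   `genes` (list of [simulate_gene()] results) and `isoforms` (list of
#'   kept-exon index vectors per gene).
#' @export
simulate_genome_annotation <- function(n_genes = 3L, seed = 1L) {
  genes <- list(); isoforms <- list()
  chrs <- character(n_genes); seqs <- character(n_genes)
  feats <- list()
  for (gi in seq_len(n_genes)) {
    strand <- if (gi %% 2L == 0L) "-" else "+"
    n_ex <- with_seed(seed * 1000L + gi, sample(2:5, 1L))
    gene <- simulate_gene(n_ex, exon_len_range = c(30L, 120L),
                          intron_len_range = c(15L, 60L),
                          seed = seed * 1000L + gi,
                          chrom = sprintf("chr%d", gi), strand = strand)
    n_iso <- with_seed(seed * 2000L + gi, sample(1:3, 1L))
    iso <- simulate_isoforms(gene, n_iso, seed = seed * 2000L + gi,
                             cluster_id = sprintf("gene%d", gi))
    genes[[gi]] <- gene; isoforms[[gi]] <- iso$kept
    chrs[gi] <- gene$chrom; seqs[gi] <- gene$genome_seq
    for (ti in seq_len(n_iso)) {
      ix <- iso$kept[[ti]]
      feats[[length(feats) + 1L]] <- data.frame(
        chrom = gene$chrom,
        start = gene$exons$start[ix] + 1L,
        end = gene$exons$end[ix],
        strand = strand,
        gene_id = sprintf("gene%d", gi),
        transcript_id = sprintf("gene%d.iso%d", gi, ti))
    }
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chrs
  fd <- do.call(rbind, feats)
  ann <- GenomicRanges::GRanges(
    seqnames = factor(fd$chrom, levels = chrs),
    ranges = IRanges::IRanges(fd$start, fd$end),
    strand = fd$strand, type = "exon",
    gene_id = fd$gene_id, transcript_id = fd$transcript_id)
  list(genome = genome, annotation = ann,
       genes = genes, isoforms = isoforms)
}
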
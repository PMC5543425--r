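# Genome-based construction, transcript projection, chains and lifting.

test_that("flatten_gene unions, merges adjacency, and rejects mixed strands", {
  f <- flatten_gene(data.frame(start = c(100L, 150L, 300L),
                               end = c(200L, 250L, 400L)), "g")
  expect_equal(f$exon_union, data.frame(start = c(100L, 300L),
                                        end = c(250L, 400L)),
               ignore_attr = TRUE)
  expect_equal(f$st_length, 250L)

  f2 <- flatten_gene(data.frame(start = c(100L, 200L),
                                end = c(200L, 300L)), "g")
  expect_equal(nrow(f2$exon_union), 1L)
  expect_equal(f2$st_length, 200L)

  expect_error(flatten_gene(data.frame(start = 1L, end = c(5L, 9L),
                                       strand = c("+", "-"),
                                       chrom = "c"), "gX"), "gX")
})

test_that("transcript exons project through cumulative offsets", {
  f <- flatten_gene(data.frame(start = c(100L, 300L), end = c(250L, 400L),
                               strand = "+", chrom = "c"), "g")
  p <- project_transcripts(f, list(tx = data.frame(start = c(100L, 300L),
                                                   end = c(200L, 400L))))
  expect_equal(p$tx, data.frame(st_start = c(0L, 150L),
                                st_end = c(100L, 250L)), ignore_attr = TRUE)
  # covering the whole union collapses to one interval
  p2 <- project_transcripts(f, list(tx = data.frame(start = c(100L, 300L),
                                                    end = c(250L, 400L))))
  expect_equal(nrow(p2$tx), 1L)
  expect_equal(p2$tx$st_end, 250L)
  expect_error(project_transcripts(
    f, list(tx = data.frame(start = 260L, end = 290L))), "union")
})

test_that("genome superTranscripts match union lengths and spliced cDNA on both strands", {
  gm <- simulate_genome_annotation(n_genes = 6, seed = 17)
  fa <- tempfile(fileext = ".fa"); gtf <- tempfile(fileext = ".gtf")
  Biostrings::writeXStringSet(gm$genome, fa)
  rtracklayer::export(gm$annotation, gtf, format = "gtf")
  res <- build_genome_st(fa, gtf)
  expect_length(res$sts, 6L)
  for (gi in seq_along(gm$genes)) {
    gid <- sprintf("gene%d", gi)
    gene <- gm$genes[[gi]]
    st <- res$sts[[gid]]
    expect_equal(nchar(st$sequence), gene$union_length)
    # minus-strand genes read 5'->3'
    concat <- paste(substring(gene$genome_seq, gene$exons$start + 1,
                              gene$exons$end), collapse = "")
    expect_equal(st$sequence,
                 if (gene$strand == "-") revcomp(concat) else concat)
    for (tx in names(st$paths)) {
      iso_i <- as.integer(sub(".*iso", "", tx))
      ix <- gm$isoforms[[gi]][[iso_i]]
      cdna <- paste(substring(gene$genome_seq, gene$exons$start[ix] + 1,
                              gene$exons$end[ix]), collapse = "")
      if (gene$strand == "-") cdna <- revcomp(cdna)
      expect_equal(path_sequence(st, tx), cdna, info = tx)
    }
    # blocks partition the superTranscript
    b <- res$blocks[[gid]]
    expect_equal(sum(b$st_end - b$st_start), gene$union_length)
  }
})

test_that("lift round-trips every position and agrees with rtracklayer liftOver", {
  gm <- simulate_genome_annotation(n_genes = 4, seed = 23)
  fa <- tempfile(fileext = ".fa"); gtf <- tempfile(fileext = ".gtf")
  Biostrings::writeXStringSet(gm$genome, fa)
  rtracklayer::export(gm$annotation, gtf, format = "gtf")
  res <- build_genome_st(fa, gtf)
  cf <- tempfile(fileext = ".chain")
  write_chain(res$chains, cf)
  reread <- read_chain(cf)
  imported <- rtracklayer::import.chain(cf)
  for (gid in names(res$chains)) {
    ch <- res$chains[[gid]]
    p <- 0:(ch$st_size - 1L)
    lf <- lift(ch, p)
    expect_true(all(lf$mapped))
    expect_equal(lift_inverse(ch, lf$genome_position), p)
    # strictly monotone within each segment
    seg <- ch$segments
    for (i in seq_len(nrow(seg))) {
      gp <- lf$genome_position[p >= seg$st_start[i] &
                               p < seg$st_start[i] + seg$len[i]]
      expect_true(all(diff(gp) == if (ch$strand == "+") 1L else -1L))
    }
    # file round trip preserves the segment table
    expect_equal(reread[[gid]]$segments, ch$segments, ignore_attr = TRUE)
    # independent cross-check: rtracklayer's liftOver on the same file
    gr <- GenomicRanges::GRanges(gid, IRanges::IRanges(p + 1L, width = 1L))
    lo <- unlist(rtracklayer::liftOver(gr, imported))
    expect_length(lo, ch$st_size)
    expect_equal(GenomicRanges::start(lo) - 1L, lf$genome_position)
  }
})

test_that("chain arithmetic matches the worked two-segment example", {
  ch <- structure(list(st_id = "g", st_size = 250L, chrom = "chr1",
                       chrom_size = 1000L, strand = "+",
                       segments = data.frame(st_start = c(0L, 150L),
                                             len = c(150L, 100L),
                                             g_start = c(100L, 300L))),
                  class = "st_chain")
  expect_equal(lift(ch, 160L)$genome_position, 310L)
  expect_equal(lift(ch, 0L)$genome_position, 100L)
})

test_that("unaligned superTranscript stretches lift as unmapped", {
  ch <- structure(list(st_id = "g", st_size = 100L, chrom = "chr1",
                       chrom_size = 1000L, strand = "+",
                       segments = data.frame(st_start = 10L, len = 50L,
                                             g_start = 500L)),
                  class = "st_chain")
  lf <- lift(ch, c(0L, 10L, 59L, 60L, 99L))
  expect_equal(lf$mapped, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(lf$genome_position[2:3], c(500L, 549L))
})

test_that("chain_from_alignment keeps the best hit after excluding _alt targets", {
  mk <- function(target, score, len = 50L)
    st_alignment("st1", target, "+",
                 data.frame(q_start = 0L, t_start = 10L, length = len),
                 1.0, score)
  sizes <- c(chr1 = 1000L, chr2 = 1000L, chr1_alt = 1000L)
  best <- chain_from_alignment("st1", 50L,
                               list(mk("chr2", 300L), mk("chr1", 500L)),
                               sizes)
  expect_equal(best$chrom, "chr1")
  alt <- chain_from_alignment("st1", 50L,
                              list(mk("chr1", 400L), mk("chr1_alt", 450L)),
                              sizes)
  expect_equal(alt$chrom, "chr1")
  expect_null(chain_from_alignment("st1", 50L, list(), sizes))
})
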
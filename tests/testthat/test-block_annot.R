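# Standard (path-derived) and dynamic (read-derived) block annotation.

two_path_st <- function() {
  super_transcript("g1", paste(rep("A", 9), collapse = ""),
                   paths = list(t1 = data.frame(st_start = 0L, st_end = 6L),
                                t2 = data.frame(st_start = c(0L, 6L),
                                                st_end = c(3L, 9L))))
}

test_that("standard blocks come from path endpoints and partition [0, L)", {
  st <- two_path_st()
  b <- standard_blocks(st)
  expect_equal(b$st_start, c(0L, 3L, 6L))
  expect_equal(b$st_end, c(3L, 6L, 9L))

  # single transcript, single interval: one block
  st1 <- super_transcript("g2", "ACGTACGT",
                          paths = list(t1 = data.frame(st_start = 0L,
                                                       st_end = 8L)))
  expect_equal(nrow(standard_blocks(st1)), 1L)

  # randomized fixtures: boundary set equals the brute-force endpoint set
  set.seed(21)
  for (i in 1:10) {
    x <- make_assembled(seed = 600 + i, n_exons = sample(2:5, 1),
                        n_iso = sample(2:6, 1))
    b <- standard_blocks(x$st)
    L <- nchar(x$st$sequence)
    expect_equal(sort(unique(c(b$st_start, b$st_end))),
                 oracle_boundaries(x$st$paths, L))
    expect_equal(sum(b$st_end - b$st_start), L)      # partition: total length
    expect_true(all(b$st_start[-1L] == b$st_end[-nrow(b)]))  # and contiguity
  }
})

test_that("two isoforms differing by one skipped exon give exactly 3 blocks", {
  gene <- simulate_gene(3, seed = 71)
  exlens <- gene$exons$end - gene$exons$start
  iso <- list(
    all = paste(vapply(1:3, function(i)
      substring(gene$genome_seq, gene$exons$start[i] + 1, gene$exons$end[i]),
      character(1)), collapse = ""),
    skip = paste(vapply(c(1, 3), function(i)
      substring(gene$genome_seq, gene$exons$start[i] + 1, gene$exons$end[i]),
      character(1)), collapse = ""))
  st <- assemble_cluster(st_cluster("g", c("a", "s"),
                                    c(iso$all, iso$skip)))
  b <- standard_blocks(st)
  expect_equal(nrow(b), 3L)
  expect_equal(b$st_end - b$st_start, exlens)
})

test_that("junctions are extracted from CIGAR N ops with overhang filtering", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:st1\tLN:200",
    # POS 11, 30M20N40M -> junction left = 40, right = 60
    paste("r1", 0, "st1", 11, 60, "30M20N40M", "*", 0, 0,
          strrep("A", 70), "*", sep = "\t"),
    # unspliced
    paste("r2", 0, "st1", 1, 60, "76M", "*", 0, 0,
          strrep("A", 76), "*", sep = "\t"),
    # two N ops: junctions (20,30) and (50,60)
    paste("r3", 0, "st1", 1, 60, "20M10N20M10N20M", "*", 0, 0,
          strrep("A", 60), "*", sep = "\t"),
    # overhang 5 < 12 on the left: ignored
    paste("r4", 0, "st1", 36, 60, "5M20N40M", "*", 0, 0,
          strrep("A", 45), "*", sep = "\t"),
    # unmapped and secondary records are ignored
    paste("r5", 4, "*", 0, 0, "*", "*", 0, 0, strrep("A", 20), "*", sep = "\t"),
    paste("r6", 256, "st1", 11, 60, "30M20N40M", "*", 0, 0,
          strrep("A", 70), "*", sep = "\t")), sam)
  j <- extract_junctions(sam, min_overhang = 12)
  expect_equal(j$left, c(20L, 40L, 50L))
  expect_equal(j$right, c(30L, 60L, 60L))
  expect_equal(j$support, c(1L, 1L, 1L))
})

test_that("records running beyond the reference are skipped with a warning", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6", "@SQ\tSN:st1\tLN:60",
    paste("r1", 0, "st1", 11, 60, "30M20N40M", "*", 0, 0,
          strrep("A", 70), "*", sep = "\t")), sam)
  expect_warning(j <- extract_junctions(sam, min_overhang = 12), "beyond")
  expect_equal(nrow(j), 0L)
})

test_that("dynamic blocks respect the five-read support threshold", {
  st <- super_transcript("g1", strrep("A", 100),
                         paths = list(t1 = data.frame(st_start = 0L,
                                                      st_end = 100L)))
  j5 <- data.frame(st_id = "g1", left = 50L, right = 70L, support = 5L)
  b <- dynamic_blocks(st, j5, min_support = 5)
  expect_equal(b$st_start, c(0L, 50L, 70L))
  expect_equal(b$st_end, c(50L, 70L, 100L))

  j4 <- transform(j5, support = 4L)
  expect_equal(nrow(dynamic_blocks(st, j4, min_support = 5)), 1L)

  none <- data.frame(st_id = character(), left = integer(),
                     right = integer(), support = integer())
  expect_equal(nrow(dynamic_blocks(st, none)), 1L)
})

test_that("raising min_support never adds boundaries (monotone)", {
  st <- super_transcript("g1", strrep("A", 300),
                         paths = list(t1 = data.frame(st_start = 0L,
                                                      st_end = 300L)))
  set.seed(8)
  j <- data.frame(st_id = "g1",
                  left = c(20L, 60L, 100L, 150L, 200L),
                  right = c(40L, 80L, 120L, 170L, 220L),
                  support = c(1L, 3L, 5L, 7L, 10L))
  prev <- NULL
  for (ms in 1:10) {
    b <- dynamic_blocks(st, j, min_support = ms)
    bnd <- sort(unique(c(b$st_start, b$st_end)))
    if (!is.null(prev)) expect_true(all(bnd %in% prev))
    prev <- bnd
    expect_equal(sum(b$st_end - b$st_start), 300L)
  }
})

test_that("simulated spliced reads reproduce the requested support and thresholds", {
  gene <- simulate_gene(3, seed = 91)
  iso <- simulate_isoforms(gene, 2, keep_prob = 0.3, seed = 92)
  sam <- tempfile(fileext = ".sam")
  simulate_spliced_reads("gene1", iso$union_length, iso$truth_paths,
                         per_junction_support = 5, seed = 1, path = sam)
  j <- extract_junctions(sam, min_overhang = 12)
  expect_true(all(j$support == 5L))
  expect_gte(nrow(j), 1L)
  st <- super_transcript("gene1", iso$union_sequence,
                         paths = iso$truth_paths[1])
  b5 <- dynamic_blocks(st, j, min_support = 5)
  b6 <- dynamic_blocks(st, j, min_support = 6)
  expect_gt(nrow(b5), 1L)
  expect_equal(nrow(b6), 1L)
  # dynamic boundaries are a subset of true exon-junction positions
  truth_bnd <- oracle_boundaries(iso$truth_paths, iso$union_length)
  expect_true(all(c(b5$st_start, b5$st_end) %in% truth_bnd))
  # support 0: no spliced reads at all
  sam0 <- tempfile(fileext = ".sam")
  simulate_spliced_reads("gene1", iso$union_length, iso$truth_paths,
                         per_junction_support = 0, seed = 1, path = sam0)
  expect_equal(nrow(extract_junctions(sam0, min_overhang = 12)), 0L)
})

test_that("annotate tags block features with their mode", {
  st <- two_path_st()
  a <- annotate(st, "standard")
  expect_equal(nrow(a$blocks), 3L)
  ex <- a$features[a$features$type == "exon"]
  expect_true(all(ex$source == "standard"))
  d <- annotate(st, "dynamic",
                junctions = data.frame(st_id = "g1", left = 3L, right = 6L,
                                       support = 9L))
  ex2 <- d$features[d$features$type == "exon"]
  expect_true(all(ex2$source == "dynamic"))
  expect_error(annotate(st, "dynamic"), "junction")
})
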
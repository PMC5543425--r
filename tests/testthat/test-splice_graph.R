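# The assembly core: build, merge, compact, cycle breaking, topological
# sort, end-to-end assembly.

test_that("base graph has one node per base and per-transcript chain edges", {
  g1 <- build_graph(st_cluster("a", "t1", "ACG"))
  expect_equal(graph_summary(g1), list(n_nodes = 3L, n_edges = 2L))

  g2 <- build_graph(st_cluster("b", c("t1", "t2"), c("ACGT", "ACGTCC")))
  expect_equal(graph_summary(g2), list(n_nodes = 10L, n_edges = 8L))

  expect_error(build_graph(list()), "st_cluster")
})

test_that("merging unions aligned bases and compaction leaves the fork structure", {
  cl <- st_cluster("g", c("t1", "t2"), c("AAACCC", "AAAGGG"))
  g <- build_graph(cl)
  merge_alignment(g, st_alignment("t1", "t2", "+",
                                  data.frame(q_start = 0L, t_start = 0L,
                                             length = 3L), 1.0, 3L))
  expect_equal(graph_summary(g)$n_nodes, 9L)   # union-find: 12 bases, 3 unions
  gc <- compact(g)
  expect_equal(nrow(gc$nodes), 3L)
  expect_setequal(gc$nodes$bases, c("AAA", "CCC", "GGG"))
  st <- topo_sort(break_cycles(gc))
  expect_equal(st$sequence, "AAACCCGGG")
  expect_equal(st$paths$t1, data.frame(st_start = 0L, st_end = 6L),
               ignore_attr = TRUE)
  expect_equal(st$paths$t2,
               data.frame(st_start = c(0L, 6L), st_end = c(3L, 9L)),
               ignore_attr = TRUE)
})

test_that("self-alignment is a no-op and repeat-violating blocks are rejected", {
  cl <- st_cluster("g", "t1", "ACGTACGT")
  g <- build_graph(cl)
  merge_alignment(g, st_alignment("t1", "t1", "+",
                                  data.frame(q_start = 0L, t_start = 0L,
                                             length = 8L), 1.0, 8L))
  expect_equal(graph_summary(g)$n_nodes, 8L)
  expect_equal(g$rejected_blocks, 0L)
  # unifying offset 0 with offset 4 of the same transcript must be rejected
  merge_alignment(g, st_alignment("t1", "t1", "+",
                                  data.frame(q_start = 0L, t_start = 4L,
                                             length = 4L), 1.0, 4L))
  expect_equal(graph_summary(g)$n_nodes, 8L)
  expect_equal(g$rejected_blocks, 1L)
})

test_that("letter-conflicting blocks are rejected atomically", {
  cl <- st_cluster("g", c("t1", "t2"), c("AAAA", "AATA"))
  g <- build_graph(cl)
  merge_alignment(g, st_alignment("t1", "t2", "+",
                                  data.frame(q_start = 0L, t_start = 0L,
                                             length = 4L), 0.75, 3L))
  expect_equal(graph_summary(g)$n_nodes, 8L)   # whole block rejected
  expect_equal(g$rejected_blocks, 1L)
})

test_that("fully merged identical transcripts compact to a single node", {
  cl <- st_cluster("g", c("t1", "t2"), c("ACGTACGTAC", "ACGTACGTAC"))
  st <- assemble_cluster(cl, min_block_len = 5, k = 5)
  expect_equal(st$sequence, "ACGTACGTAC")
  expect_equal(st$paths$t2, data.frame(st_start = 0L, st_end = 10L),
               ignore_attr = TRUE)
})

test_that("the shared-repeat cluster cycles and breaks as the oracle predicts", {
  rf <- repeat_fixture()
  g <- build_graph(rf)
  for (a in cluster_alignments(rf, min_block_len = 3, k = 3))
    merge_alignment(g, a)
  gc <- compact(g)
  edges <- superTx:::derive_edges(gc$occ)
  cyc <- superTx:::find_cycle(edges, nrow(gc$nodes))
  expect_false(is.null(cyc))                       # pre-break graph cycles
  gd <- break_cycles(gc)
  expect_null(superTx:::find_cycle(superTx:::derive_edges(gd$occ),
                                   nrow(gd$nodes)))
  # the duplicated node is a minimal-size cycle node
  dup <- gd$duplicated_nodes
  expect_length(dup, 1L)
  expect_equal(gc$nodes$len[dup], min(gc$nodes$len[cyc]))
  st <- topo_sort(gd)
  expect_equal(st$sequence, attr(rf, "expected_sequence"))
  expect_equal(nchar(st$sequence), 15L)
  expect_true(reconstructs_all(st, rf))
  # acyclic graphs pass through break_cycles unchanged
  cl <- st_cluster("g", "t1", "ACGTAC")
  gd2 <- break_cycles(compact(build_graph(cl)))
  expect_equal(topo_sort(gd2)$sequence, "ACGTAC")
})

test_that("assembly degenerate cases: identity, containment, no-overlap", {
  cl1 <- st_cluster("g1", "t1", "ACGTACGTACGTAGCT")
  expect_equal(assemble_cluster(cl1)$sequence, cl1$seqs[1])

  set.seed(9)
  t1 <- random_dna_str(200)
  t2 <- substr(t1, 51, 150)                     # strict substring
  st <- assemble_cluster(st_cluster("g2", c("t1", "t2"), c(t1, t2)))
  expect_equal(st$sequence, t1)
  expect_equal(nrow(st$paths$t2), 1L)
  expect_equal(st$paths$t2$st_start, 50L)

  # no alignment at all: concatenation in anchor (input-rank) order
  a <- random_dna_str(40); b <- random_dna_str(40)
  st2 <- assemble_cluster(st_cluster("g3", c("t1", "t2"), c(a, b)),
                          min_block_len = 25)
  expect_equal(st2$sequence, paste0(a, b))
})

test_that("the 50-transcript cap selects the first 50 by input order", {
  set.seed(3)
  base <- random_dna_str(120)
  seqs <- c(rep(base, 55), replicate(5, random_dna_str(60)))
  cl <- st_cluster("cap", sprintf("t%02d", 1:60), seqs)
  st <- assemble_cluster(cl)
  expect_length(st$used_transcripts, 50L)
  expect_equal(st$skipped_transcripts, sprintf("t%02d", 51:60))
  expect_equal(st$sequence, base)               # all 50 identical
})

test_that("reconstruction and non-redundancy hold on randomized gene fixtures", {
  set.seed(101)
  for (i in 1:15) {
    gene <- simulate_gene(sample(1:5, 1), seed = 100 + i)
    iso <- simulate_isoforms(gene, sample(1:8, 1), seed = 200 + i,
                             cluster_id = "g")
    st <- assemble_cluster(iso$cluster)
    expect_true(reconstructs_all(st, iso$cluster), info = paste("gene", i))
    expect_equal(nchar(st$sequence), iso$union_length,
                 info = paste("gene", i))
    # every base covered by at least one path
    cov <- logical(nchar(st$sequence))
    for (p in st$paths)
      for (j in seq_len(nrow(p)))
        cov[(p$st_start[j] + 1):p$st_end[j]] <- TRUE
    expect_true(all(cov))
  }
})

test_that("output is invariant to transcript id relabeling", {
  gene <- simulate_gene(4, seed = 55)
  iso <- simulate_isoforms(gene, 3, seed = 56, cluster_id = "g")
  cl <- iso$cluster
  st1 <- assemble_cluster(cl)
  cl2 <- st_cluster("g", c("zz", "aa", "mm"), cl$seqs)
  st2 <- assemble_cluster(cl2)
  expect_equal(st2$sequence, st1$sequence)
  expect_equal(unname(st2$paths), unname(st1$paths[cl$ids]))
})

test_that("assembly is deterministic and independent of worker count", {
  clusters <- lapply(1:4, function(i) {
    iso <- simulate_isoforms(simulate_gene(3, seed = 300 + i), 3,
                             seed = 400 + i, cluster_id = paste0("g", i))
    iso$cluster
  })
  names(clusters) <- paste0("g", 1:4)
  r1 <- assemble_clusters(clusters, cores = 1)
  r2 <- assemble_clusters(clusters, cores = 2)
  expect_equal(lapply(r1, `[[`, "sequence"), lapply(r2, `[[`, "sequence"))
  expect_equal(lapply(r1, `[[`, "paths"), lapply(r2, `[[`, "paths"))
})

test_that("every emitted superTranscript admits its transcripts (exhaustive small clusters)", {
  set.seed(500)
  for (i in 1:40) {
    n <- sample(1:3, 1)
    seqs <- vapply(seq_len(n),
                   function(j) random_dna_str(sample(5:20, 1),
                                              alphabet = c("A", "C", "G")),
                   character(1))
    cl <- st_cluster("s", paste0("t", seq_len(n)), seqs)
    st <- assemble_cluster(cl, min_block_len = 3, k = 3)
    flipped <- attr(st, "flipped")
    for (j in seq_len(n)) {
      s <- if (cl$ids[j] %in% flipped) revcomp(seqs[j]) else seqs[j]
      expect_true(oracle_admits(st$sequence, s),
                  info = paste("case", i, "tx", j))
    }
  }
})
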
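# Independent oracles used across the suite. These deliberately use
# different algorithm families from the implementation they check.

# Best co-linear gapless-chain score between a and b with all blocks of
# length >= m, by closed-form prefix DP over the full match matrix
# (O(n^2 * n) at the tiny sizes used). Independent of seed-and-chain.
oracle_chain_score <- function(a, b, m) {
  a <- strsplit(a, "", fixed = TRUE)[[1]]
  b <- strsplit(b, "", fixed = TRUE)[[1]]
  la <- length(a); lb <- length(b)
  run <- matrix(0L, la + 1L, lb + 1L)   # exact-run length ending at (i, j)
  S <- matrix(0L, la + 1L, lb + 1L)     # best chain score over prefixes
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      if (a[i] == b[j]) run[i + 1L, j + 1L] <- run[i, j] + 1L
      best <- max(S[i, j + 1L], S[i + 1L, j])
      r <- run[i + 1L, j + 1L]
      if (r >= m) {
        # a block of any length l in m..r ending at (i, j)
        for (l in m:r) best <- max(best, S[i - l + 1L, j - l + 1L] + l)
      }
      S[i + 1L, j + 1L] <- best
    }
  }
  S[la + 1L, lb + 1L]
}

# Is `tx` expressible as an ordered chain of non-overlapping substrings of
# `st`? Equivalent to tx being a subsequence of st; greedy check.
oracle_admits <- function(st, tx) {
  s <- strsplit(st, "", fixed = TRUE)[[1]]
  t <- strsplit(tx, "", fixed = TRUE)[[1]]
  i <- 1L
  for (ch in t) {
    while (i <= length(s) && s[i] != ch) i <- i + 1L
    if (i > length(s)) return(FALSE)
    i <- i + 1L
  }
  TRUE
}

# Brute-force block boundary set from transcript paths.
oracle_boundaries <- function(paths, L) {
  sort(unique(c(0L, L, unlist(lapply(paths, function(p)
    c(p$st_start, p$st_end))))))
}

# Reconstruction check against the (possibly re-oriented) inputs.
reconstructs_all <- function(st, cluster) {
  flipped <- attr(st, "flipped")
  all(vapply(st$used_transcripts, function(tx) {
    s <- cluster$seqs[match(tx, cluster$ids)]
    if (!is.null(flipped) && tx %in% flipped) s <- revcomp(s)
    path_sequence(st, tx) == s
  }, logical(1)))
}

random_dna_str <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Small standard fixture: one gene + isoforms, assembled.
make_assembled <- function(seed = 42L, n_exons = 4L, n_iso = 3L) {
  gene <- simulate_gene(n_exons, seed = seed)
  iso <- simulate_isoforms(gene, n_iso, seed = seed + 1L,
                           cluster_id = sprintf("g%d", seed))
  list(gene = gene, iso = iso, st = assemble_cluster(iso$cluster))
}
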
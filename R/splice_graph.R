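# The assembly core: a base-level directed graph per cluster, merged along
# pairwise alignments (union-find), compacted to maximal non-branching runs,
# made acyclic by node duplication, and topologically sorted into the
# superTranscript.
#
# Representation. A base-level graph is a union-find over the B bases of the
# cluster (global base index = transcript offset + transcript start). A
# compacted graph holds nodes (run of bases each) plus the occurrence table
# (transcript, offset, node): each transcript's walk is its occurrences in
# offset order, and the edge set is derived from consecutive walk pairs, so
# transcript paths are walks by construction at every stage.

#' Build the base-level splice graph of a cluster
#'
#' One node per transcript base; for each transcript an edge from every base
#' to its successor. No inter-transcript edges exist until alignments are
#' merged in with [merge_alignment()].
#'
#' @param cluster an [st_cluster] (already strand-normalised if needed).
#' @return An object of class `st_splice_graph` (stage `"base"`).
#' @export
build_graph <- function(cluster) {
  if (!inherits(cluster, "st_cluster") || length(cluster$ids) == 0L)
    stop("build_graph requires a non-empty st_cluster")
  lens <- nchar(cluster$seqs)
  starts <- c(0L, cumsum(lens))[seq_along(lens)]   # global start per transcript
  B <- sum(lens)
  letters <- unlist(strsplit(cluster$seqs, "", fixed = TRUE), use.names = FALSE)
  txof <- rep.int(seq_along(lens), lens)
  offof <- unlist(lapply(lens, function(l) seq_len(l) - 1L), use.names = FALSE)
  g <- new.env(parent = emptyenv())
  g$cluster <- cluster
  g$starts <- starts
  g$lens <- lens
  g$B <- B
  g$letters <- letters
  g$txof <- txof
  g$offof <- offof
  g$parent <- seq_len(B)
  g$size <- rep.int(1L, B)
  g$memtx <- vector("list", B)      # NULL = singleton {txof[root]}
  g$rejected_blocks <- 0L
  class(g) <- "st_splice_graph"
  attr(g, "stage") <- "base"
  g
}

# vectorised find with path compression
uf_find <- function(g, x) {
  r <- x
  repeat {
    pr <- g$parent[r]
    if (identical(pr, r)) break
    r <- pr
  }
  g$parent[x] <- r
  r
}

memtx_of <- function(g, root) {
  m <- g$memtx[[root]]
  if (is.null(m)) g$txof[root] else m
}

#' Merge one pairwise alignment into the base graph
#'
#' For each gapless block, base i of the query run is unified with base i of
#' the target run. A whole block is rejected (graph unchanged, rejection
#' counted) if applying it would place two distinct offsets of one
#' transcript in the same node or unify nodes holding different base
#' letters. Only `+` strand alignments are merged; `-` strand records are
#' skipped (orientation is normalised before assembly).
#'
#' @param g an `st_splice_graph` at stage `"base"`.
#' @param alignment an [st_alignment] between two cluster transcripts.
#' @return The graph, invisibly (modified in place).
#' @export
merge_alignment <- function(g, alignment) {
  stopifnot(inherits(g, "st_splice_graph"))
  if (alignment$strand != "-") {
    qi <- match(alignment$query_id, g$cluster$ids)
    ti <- match(alignment$target_id, g$cluster$ids)
    if (is.na(qi) || is.na(ti))
      stop("alignment references transcript(s) absent from the graph")
    for (bi in seq_len(nrow(alignment$blocks))) {
      b <- alignment$blocks[bi, ]
      q_idx <- g$starts[qi] + b$q_start + seq_len(b$length)
      t_idx <- g$starts[ti] + b$t_start + seq_len(b$length)
      if (!apply_block(g, q_idx, t_idx))
        g$rejected_blocks <- g$rejected_blocks + 1L
    }
  }
  invisible(g)
}

# Atomically union base pairs (q_idx[i] ~ t_idx[i]); returns FALSE (and
# leaves the graph untouched) on any letter or same-transcript conflict.
apply_block <- function(g, q_idx, t_idx) {
  rq <- uf_find(g, q_idx)
  rt <- uf_find(g, t_idx)
  act <- rq != rt
  if (!any(act)) return(TRUE)                      # all identities: no-op
  rq <- rq[act]; rt <- rt[act]
  # group the involved roots by the unions this block implies
  U <- unique(c(rq, rt))
  lp <- seq_along(U)                               # local mini union-find
  lfind <- function(x) { while (lp[x] != x) x <- lp[x]; x }
  for (i in seq_along(rq)) {
    a <- lfind(match(rq[i], U)); b <- lfind(match(rt[i], U))
    if (a != b) lp[a] <- b
  }
  groups <- split(U, vapply(seq_along(U), lfind, integer(1)))
  merged <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    roots <- groups[[gi]]
    if (length(roots) == 1L) next
    if (length(unique(g$letters[roots])) > 1L) return(FALSE)
    txs <- unlist(lapply(roots, function(r) memtx_of(g, r)), use.names = FALSE)
    if (anyDuplicated(txs)) return(FALSE)          # same-transcript conflict
    merged[[gi]] <- sort(txs)
  }
  # commit
  for (gi in seq_along(groups)) {
    roots <- groups[[gi]]
    if (length(roots) == 1L) next
    final <- roots[which.max(g$size[roots])]
    others <- setdiff(roots, final)
    g$parent[others] <- final
    g$size[final] <- sum(g$size[roots])
    g$memtx[[final]] <- merged[[gi]]
    for (r in others) g$memtx[r] <- list(NULL)
  }
  TRUE
}

#' Summary counts of a splice graph
#'
#' Node and edge counts at the current stage (distinct base classes and
#' distinct consecutive-class pairs for a base graph; compacted nodes and
#' derived walk edges otherwise).
#'
#' @param g an `st_splice_graph` (any stage).
#' @return List with `n_nodes` and `n_edges`.
#' @export
graph_summary <- function(g) {
  if (attr(g, "stage") == "base") {
    cls <- uf_find(g, seq_len(g$B))
    walks <- split(cls, g$txof)
    e <- unique(unlist(lapply(walks, function(w) {
      if (length(w) < 2L) return(character())
      paste(w[-length(w)], w[-1L])
    }), use.names = FALSE))
    list(n_nodes = length(unique(cls)), n_edges = length(e))
  } else {
    list(n_nodes = nrow(g$nodes), n_edges = nrow(derive_edges(g$occ)))
  }
}

#' @export
print.st_splice_graph <- function(x, ...) {
  s <- graph_summary(x)
  cat("st_splice_graph [", attr(x, "stage"), "] cluster '",
      x$cluster$cluster_id, "': ", s$n_nodes, " node(s), ", s$n_edges,
      " edge(s)\n", sep = "")
  invisible(x)
}

#' Compact the merged base graph
#'
#' Replaces every maximal non-branching run (interior in-degree 1,
#' out-degree 1, identical member continuity) by a single node whose bases
#' are the concatenated run, leaving the set of transcript walks unchanged.
#'
#' @param g an `st_splice_graph` at stage `"base"`.
#' @return A compacted `st_splice_graph` (stage `"compact"`) holding `nodes`
#'   (data.frame: `node`, `len`, `bases`) and `occ` (data.frame: `tx`
#'   transcript index, `off` 0-based offset of the occurrence, `node`).
#' @export
compact <- function(g) {
  stopifnot(attr(g, "stage") == "base")
  rep_ <- uf_find(g, seq_len(g$B))
  cls <- match(rep_, unique(rep_))                 # dense class id per base
  C <- max(cls)
  occ_cnt <- tabulate(cls, C)
  # adjacency counts over all transcripts
  from <- integer(); to <- integer()
  for (t in seq_along(g$lens)) {
    w <- cls[(g$starts[t] + 1L):(g$starts[t] + g$lens[t])]
    if (length(w) >= 2L) {
      from <- c(from, w[-length(w)]); to <- c(to, w[-1L])
    }
  }
  nxt <- rep.int(NA_integer_, C)
  if (length(from)) {
    key <- (as.numeric(from) - 1) * C + as.numeric(to)
    o <- order(key)
    key <- key[o]; fo <- from[o]; t2 <- to[o]
    nw <- c(TRUE, diff(key) != 0)
    ufrom <- fo[nw]; uto <- t2[nw]
    cnt <- diff(c(which(nw), length(key) + 1L))
    outdeg <- tabulate(ufrom, C)
    indeg <- tabulate(uto, C)
    ok <- outdeg[ufrom] == 1L & indeg[uto] == 1L &
          cnt == occ_cnt[ufrom] & occ_cnt[ufrom] == occ_cnt[uto]
    nxt[ufrom[ok]] <- uto[ok]
  }
  has_prev <- rep.int(FALSE, C)
  has_prev[nxt[!is.na(nxt)]] <- TRUE
  heads <- which(!has_prev)
  node_of <- rep.int(NA_integer_, C)
  node_len <- integer()
  node_head <- integer()
  nid <- 0L
  for (h in heads) {
    nid <- nid + 1L
    c0 <- h; l <- 0L
    while (!is.na(c0)) {
      node_of[c0] <- nid
      l <- l + 1L
      c0 <- nxt[c0]
    }
    node_len[nid] <- l
    node_head[nid] <- h
  }
  # occurrences: members of each head class (one per member base)
  head_bases <- split(seq_len(g$B), cls)[as.character(node_head)]
  occ <- data.frame(
    tx = unlist(lapply(head_bases, function(ix) g$txof[ix]), use.names = FALSE),
    off = unlist(lapply(head_bases, function(ix) g$offof[ix]), use.names = FALSE),
    node = rep.int(seq_len(nid), lengths(head_bases)))
  # node bases read from a representative member's transcript sequence
  first_ix <- vapply(head_bases, `[[`, integer(1), 1L)
  bases <- substring(g$cluster$seqs[g$txof[first_ix]],
                     g$offof[first_ix] + 1L,
                     g$offof[first_ix] + node_len)
  g2 <- new.env(parent = emptyenv())
  g2$cluster <- g$cluster
  g2$nodes <- data.frame(node = seq_len(nid), len = node_len, bases = bases,
                         stringsAsFactors = FALSE)
  g2$occ <- occ[order(occ$tx, occ$off), , drop = FALSE]
  g2$rejected_blocks <- g$rejected_blocks
  g2$duplicated_nodes <- integer()
  class(g2) <- "st_splice_graph"
  attr(g2, "stage") <- "compact"
  g2
}

# Edges derived from consecutive occurrences of each transcript walk.
derive_edges <- function(occ) {
  occ <- occ[order(occ$tx, occ$off), , drop = FALSE]
  n <- nrow(occ)
  if (n < 2L) return(data.frame(from = integer(), to = integer()))
  same <- occ$tx[-n] == occ$tx[-1L]
  e <- data.frame(from = occ$node[-n][same], to = occ$node[-1L][same])
  unique(e)
}

# anchor key per node: min over occurrences of (rank, offset), encoded as a
# single double rank * BIG + offset (BIG exceeds any transcript length).
anchor_keys <- function(g) {
  big <- max(nchar(g$cluster$seqs)) + 1
  ranks <- g$cluster$ranks[g$occ$tx]
  key <- ranks * big + g$occ$off
  out <- rep.int(Inf, nrow(g$nodes))
  agg <- tapply(key, g$occ$node, min)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

# Find one directed cycle (as a node sequence) by iterative DFS; NULL if
# acyclic. Deterministic: neighbours explored in ascending node order.
find_cycle <- function(edges, n_nodes) {
  if (nrow(edges) == 0L) return(NULL)
  adj <- split(edges$to, factor(edges$from, levels = seq_len(n_nodes)))
  adj <- lapply(adj, sort)
  colr <- rep.int(0L, n_nodes)                 # 0 white, 1 grey, 2 black
  parent <- rep.int(0L, n_nodes)
  for (s in seq_len(n_nodes)) {
    if (colr[s] != 0L) next
    stack <- list(list(u = s, i = 1L))
    colr[s] <- 1L
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      u <- fr$u
      nb <- adj[[u]]
      if (fr$i <= length(nb)) {
        v <- nb[fr$i]
        stack[[length(stack)]]$i <- fr$i + 1L
        if (colr[v] == 0L) {
          colr[v] <- 1L
          parent[v] <- u
          stack[[length(stack) + 1L]] <- list(u = v, i = 1L)
        } else if (colr[v] == 1L) {
          cyc <- u
          while (cyc[1L] != v) cyc <- c(parent[cyc[1L]], cyc)
          return(cyc)                          # v -> ... -> u (-> v)
        }
      } else {
        colr[u] <- 2L
        stack[[length(stack)]] <- NULL
      }
    }
  }
  NULL
}

#' Break all cycles by node duplication
#'
#' While a directed cycle exists: among its nodes the one with fewest bases
#' is selected (ties by smallest anchor, i.e. earliest input rank then
#' offset) and duplicated; the occurrences that enter the selected node via
#' the cycle's incoming edge move to the duplicate, taking their outgoing
#' continuation with them. Every transcript walk is preserved and the
#' detected cycle's closing edge disappears. On repeat-dense inputs fresh
#' duplicates can keep spawning new cycles; past a soft iteration cap the
#' smallest multi-occurrence cycle node is instead split fully into
#' per-occurrence copies, which strictly reduces node sharing and
#' guarantees termination (hard cap: total base count).
#'
#' @param g an `st_splice_graph` at stage `"compact"`.
#' @return The graph, acyclic (stage `"dag"`).
#' @export
break_cycles <- function(g) {
  stopifnot(attr(g, "stage") %in% c("compact", "dag"))
  soft_cap <- nrow(g$nodes) + nrow(g$occ)
  # phase 1 gets the spec'd base-count budget; phase 2 needs at most one
  # split per shared occurrence
  cap <- max(sum(nchar(g$cluster$seqs)), soft_cap) + nrow(g$occ) + 1L
  it <- 0L
  repeat {
    edges <- derive_edges(g$occ)
    cyc <- find_cycle(edges, nrow(g$nodes))
    if (is.null(cyc)) break
    it <- it + 1L
    if (it > cap)
      stop("cycle breaking exceeded the iteration cap (pathological input)")
    anch <- anchor_keys(g)
    occ_n <- tabulate(g$occ$node, nrow(g$nodes))
    if (it <= soft_cap) {
      lens <- g$nodes$len[cyc]
      cand <- cyc[lens == min(lens)]
      v <- cand[which.min(anch[cand])]
      pos <- match(v, cyc)
      w <- if (pos == 1L) cyc[length(cyc)] else cyc[pos - 1L]
      # occurrences of v entered from w (predecessor occurrence in the walk)
      occ <- g$occ                                # ordered by (tx, off)
      at_v <- which(occ$node == v)
      move <- at_v[vapply(at_v, function(i) {
        i > 1L && occ$tx[i - 1L] == occ$tx[i] && occ$node[i - 1L] == w
      }, logical(1))]
      if (length(move)) {
        new_id <- nrow(g$nodes) + 1L
        g$nodes <- rbind(g$nodes,
                         data.frame(node = new_id, len = g$nodes$len[v],
                                    bases = g$nodes$bases[v],
                                    stringsAsFactors = FALSE))
        g$occ$node[move] <- new_id
        g$duplicated_nodes <- c(g$duplicated_nodes, v)
        next
      }
      # fall through to a full split when no occurrence enters via w
    }
    # full split: smallest (then earliest-anchored) cycle node with >= 2
    # occurrences becomes one copy per occurrence
    cand <- cyc[occ_n[cyc] >= 2L]
    if (length(cand) == 0L)
      stop("internal error: cycle without a shared node")
    cand <- cand[g$nodes$len[cand] == min(g$nodes$len[cand])]
    v <- cand[which.min(anch[cand])]
    at_v <- which(g$occ$node == v)
    extra <- at_v[-1L]
    new_ids <- nrow(g$nodes) + seq_along(extra)
    g$nodes <- rbind(g$nodes,
                     data.frame(node = new_ids, len = g$nodes$len[v],
                                bases = g$nodes$bases[v],
                                stringsAsFactors = FALSE))
    g$occ$node[extra] <- new_ids
    g$duplicated_nodes <- c(g$duplicated_nodes, rep.int(v, length(extra)))
    # nodes that lost all occurrences become isolated and are pruned in the
    # final renumbering below (node ids must stay positional here)
  }
  # drop occurrence-less nodes and renumber densely
  live <- sort(unique(g$occ$node))
  g$nodes <- g$nodes[match(live, g$nodes$node), , drop = FALSE]
  g$occ$node <- match(g$occ$node, live)
  g$nodes$node <- seq_along(live)
  rownames(g$nodes) <- NULL
  attr(g, "stage") <- "dag"
  g
}

#' Topologically sort an acyclic splice graph into a superTranscript
#'
#' Kahn's algorithm with a deterministic total order: among ready nodes the
#' one with the smallest (component anchor, node anchor) key is emitted
#' first, so disconnected components come out whole, ordered by their
#' earliest-input-rank anchor, and within a component ties go to the
#' earliest (input rank, offset) member. The sequence is the concatenation
#' of node bases in emitted order; transcript paths map each walk onto
#' intervals of that sequence (adjacent intervals merged).
#'
#' @param g an `st_splice_graph` at stage `"dag"`.
#' @return A [super_transcript].
#' @export
topo_sort <- function(g) {
  stopifnot(attr(g, "stage") == "dag")
  N <- nrow(g$nodes)
  edges <- derive_edges(g$occ)
  anch <- anchor_keys(g)
  # connected components (undirected) for component-contiguous output
  comp <- seq_len(N)
  if (nrow(edges)) {
    cfind <- function(x) { while (comp[x] != x) x <- comp[x]; x }
    for (i in seq_len(nrow(edges))) {
      a <- cfind(edges$from[i]); b <- cfind(edges$to[i])
      if (a != b) comp[max(a, b)] <- min(a, b)
    }
    comp <- vapply(seq_len(N), cfind, integer(1))
  }
  comp_anchor <- rep.int(Inf, N)
  agg <- tapply(anch, comp, min)
  comp_anchor_by <- stats::setNames(as.numeric(agg), names(agg))
  comp_anchor <- comp_anchor_by[as.character(comp)]
  big <- max(anch[is.finite(anch)], 1) + 1
  key <- comp_anchor * big + anch
  indeg <- rep.int(0L, N)
  if (nrow(edges)) {
    tb <- tabulate(edges$to, N)
    indeg <- tb
  }
  adj <- split(edges$to, factor(edges$from, levels = seq_len(N)))
  ready <- which(indeg == 0L)
  order_out <- integer(0)
  while (length(ready)) {
    u <- ready[which.min(key[ready])]
    ready <- ready[ready != u]
    order_out <- c(order_out, u)
    for (v in adj[[u]]) {
      indeg[v] <- indeg[v] - 1L
      if (indeg[v] == 0L) ready <- c(ready, v)
    }
  }
  if (length(order_out) != N)
    stop("cycle detected during topological sort; break_cycles failed")
  pos <- integer(N)
  lens <- g$nodes$len[order_out]
  pos[order_out] <- c(0L, cumsum(lens))[seq_len(N)]
  sequence <- paste(g$nodes$bases[order_out], collapse = "")
  paths <- list()
  occ <- g$occ[order(g$occ$tx, g$occ$off), , drop = FALSE]
  for (t in unique(occ$tx)) {
    o <- occ[occ$tx == t, , drop = FALSE]
    s <- pos[o$node]
    e <- s + g$nodes$len[o$node]
    # merge adjacent intervals
    keep_start <- c(TRUE, s[-1L] != e[-length(e)])
    grp <- cumsum(keep_start)
    paths[[g$cluster$ids[t]]] <- data.frame(
      st_start = tapply(s, grp, `[[`, 1L)[],
      st_end = tapply(e, grp, function(x) x[length(x)])[],
      row.names = NULL)
  }
  paths <- lapply(paths, function(p) {
    data.frame(st_start = as.integer(p$st_start), st_end = as.integer(p$st_end))
  })
  st <- super_transcript(g$cluster$cluster_id, sequence, paths,
                         used_transcripts = g$cluster$ids[sort(unique(occ$tx))])
  attr(st, "rejected_blocks") <- g$rejected_blocks
  attr(st, "duplicated_nodes") <- length(g$duplicated_nodes)
  st
}

#' Assemble one cluster into a superTranscript
#'
#' End-to-end composition: cap to the first `max_transcripts` transcripts by
#' input rank, compute pairwise alignments (or take imported ones),
#' strand-normalise, recompute alignments if anything flipped, build the
#' base graph, merge all alignment blocks in deterministic pair order,
#' compact, break cycles and topologically sort. The reconstruction
#' invariant (every used transcript's path spells its input sequence,
#' possibly reverse-complemented by orientation) is verified before
#' returning.
#'
#' @param cluster an [st_cluster].
#' @param max_transcripts transcript cap (default 50, "first n" by rank).
#' @param min_block_len,k internal aligner parameters.
#' @param min_identity minimum identity for imported alignments to be used.
#' @param alignments optional list of [st_alignment] (e.g. from
#'   [read_psl()]) used instead of the internal aligner.
#' @return A [super_transcript] with `used_transcripts`,
#'   `skipped_transcripts` and attributes `rejected_blocks`,
#'   `duplicated_nodes` and `flipped`.
#' @export
assemble_cluster <- function(cluster, max_transcripts = 50L,
                             min_block_len = 20L, k = 11L,
                             min_identity = 0.98, alignments = NULL) {
  stopifnot(inherits(cluster, "st_cluster"))
  n_use <- min(length(cluster$ids), max_transcripts)
  skipped <- if (length(cluster$ids) > n_use)
    cluster$ids[(n_use + 1L):length(cluster$ids)] else character()
  sub <- st_cluster(cluster$cluster_id, cluster$ids[seq_len(n_use)],
                    cluster$seqs[seq_len(n_use)])
  if (is.null(alignments)) {
    alns <- cluster_alignments(sub, max_transcripts = n_use,
                               min_block_len = min_block_len, k = k)
  } else {
    alns <- Filter(function(a) a$query_id %in% sub$ids &&
                     a$target_id %in% sub$ids &&
                     a$identity >= min_identity, alignments)
  }
  oriented <- orient_cluster(sub, alns)
  if (length(attr(oriented, "flipped")))
    alns <- cluster_alignments(oriented, max_transcripts = n_use,
                               min_block_len = min_block_len, k = k)
  g <- build_graph(oriented)
  for (al in alns) merge_alignment(g, al)
  st <- topo_sort(break_cycles(compact(g)))
  st$skipped_transcripts <- skipped
  attr(st, "flipped") <- attr(oriented, "flipped")
  for (tx in st$used_transcripts) {
    expect <- oriented$seqs[match(tx, oriented$ids)]
    if (!identical(path_sequence(st, tx), expect))
      stop("internal error: reconstruction failed for transcript ", tx,
           " in cluster ", cluster$cluster_id)
  }
  st
}

#' Assemble many clusters (optionally in parallel)
#'
#' Per-cluster independence allows process-level parallelism; results are
#' returned in cluster order and are independent of the worker count.
#'
#' @param clusters named list of [st_cluster].
#' @param cores number of worker processes (forked; 1 = serial).
#' @param ... passed to [assemble_cluster()].
#' @return Named list of [super_transcript].
#' @export
assemble_clusters <- function(clusters, cores = 1L, ...) {
  run <- function(cl) assemble_cluster(cl, ...)
  res <- if (cores > 1L) {
    parallel::mclapply(clusters, run, mc.cores = cores)
  } else {
    lapply(clusters, run)
  }
  stats::setNames(res, names(clusters))
}
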
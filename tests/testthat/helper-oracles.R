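# Independent brute-force oracles used to cross-check the package's
# algorithmic cores at small scale. Each oracle deliberately avoids the code
# path it verifies.

# All k-subsets of the vertex names that induce complete subgraphs.
brute_k_cliques <- function(g, k) {
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
  if (length(nm) < k) return(list())
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  rownames(adj) <- colnames(adj) <- nm
  combos <- utils::combn(sort(nm), k, simplify = FALSE)
  Filter(function(s) {
    pairs <- utils::combn(s, 2, simplify = FALSE)
    all(vapply(pairs, function(p) adj[p[1], p[2]] > 0, logical(1)))
  }, combos)
}

# Brute-force clique percolation: k-cliques adjacent iff sharing k-1 nodes;
# communities = components of the clique adjacency (checked by direct
# pairwise comparison, no hashing).
brute_cpm <- function(g, k) {
  cl <- brute_k_cliques(g, k)
  n <- length(cl)
  if (!n) return(list())
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j)
    adj[i, j] <- adj[j, i] <- length(intersect(cl[[i]], cl[[j]])) == k - 1
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comms <- lapply(split(seq_len(n), comp), function(idx)
    sort(unique(unlist(cl[idx]))))
  comms[order(vapply(comms, paste, character(1), collapse = "\r"))]
}

# Exhaustive best chain score over all orientation-consistent monotone anchor
# subsets obeying the gap constraint (anchors: data.frame q_rank, s_rank).
brute_best_chain_score <- function(anc, max_gap = 25, match_score = 50,
                                   gap_penalty = -1) {
  n <- nrow(anc)
  best <- -Inf
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (!length(idx)) next
    for (o in c(1, -1)) {
      sub <- anc[idx, , drop = FALSE]
      sub <- sub[order(sub$q_rank), , drop = FALSE]
      ok <- TRUE
      score <- match_score
      if (nrow(sub) > 1) {
        for (t in 2:nrow(sub)) {
          dq <- sub$q_rank[t] - sub$q_rank[t - 1]
          ds <- o * (sub$s_rank[t] - sub$s_rank[t - 1])
          if (dq <= 0 || dq > max_gap || ds <= 0 || ds > max_gap) {
            ok <- FALSE
            break
          }
          score <- score + match_score + gap_penalty * ((dq - 1) + (ds - 1))
        }
      }
      if (ok) best <- max(best, score)
    }
  }
  best
}

# Bipartition oracle built on igraph components: a leaf set is monophyletic
# iff deleting some edge of the (unrooted) tree graph separates exactly it.
brute_monophyletic <- function(tree, leaves) {
  ut <- ape::unroot(tree)
  ntip <- length(ut$tip.label)
  edges <- ut$edge
  labs <- c(ut$tip.label, paste0("internal_", seq_len(ut$Nnode)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = labs[edges[, 1]], to = labs[edges[, 2]]),
    directed = FALSE, vertices = labs)
  target <- sort(unique(leaves))
  if (length(target) <= 1 || length(target) == ntip) return(TRUE)
  for (e in seq_len(igraph::ecount(g))) {
    h <- igraph::delete_edges(g, e)
    comp <- igraph::components(h)$membership
    side <- sort(intersect(names(comp)[comp == comp[[target[1]]]],
                           ut$tip.label))
    if (identical(side, target)) return(TRUE)
  }
  FALSE
}

# Random attributed test graph with vertex names.
random_named_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::set_vertex_attr(g, "name", value = sprintf("v%02d", seq_len(n)))
}
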
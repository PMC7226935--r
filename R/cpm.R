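# Overlapping community detection by the clique percolation method (CPM):
# communities are connected components of the clique graph in which two
# k-cliques are adjacent iff they share exactly k-1 nodes. Unweighted CPM,
# matching CFinder's definition; nodes may belong to several communities.

#' Enumerate all k-cliques of a graph
#'
#' Exact enumeration (via igraph's clique machinery); each clique is reported
#' once as a sorted node-name tuple.
#'
#' @param graph An igraph (undirected) or a `synteny_network`.
#' @param k Clique size (>= 2).
#' @return List of character vectors (sorted node names).
#' @export
enumerate_k_cliques <- function(graph, k) {
  if (k < 2) stop("k must be >= 2")
  g <- if (inherits(graph, "synteny_network")) graph$graph else graph
  if (is.null(igraph::V(g)$name))
    g <- igraph::set_vertex_attr(g, "name",
                                 value = as.character(seq_len(igraph::vcount(g))))
  cl <- igraph::cliques(g, min = k, max = k)
  out <- lapply(cl, function(x) sort(igraph::V(g)$name[as.integer(x)]))
  out[order(vapply(out, paste, character(1), collapse = "\r"))]
}

# union-find over seq_len(n)
.uf_new <- function(n) seq_len(n)
.uf_find <- function(uf, i) {
  while (uf[i] != i) i <- uf[i]
  i
}

#' Clique percolation communities
#'
#' Communities are the connected components of the k-clique adjacency graph
#' (two k-cliques adjacent iff they share exactly k-1 nodes); a community's
#' node set is the union of its cliques. Nodes can belong to several
#' communities; nodes in no k-clique are unassigned. Community ids are
#' assigned by descending size, then by lexicographically smallest member,
#' so numbering is deterministic.
#'
#' @param graph An igraph or `synteny_network`.
#' @param k Clique size threshold (>= 3; default 3).
#' @return Object of class `clique_communities`: list of communities, each
#'   `list(id, nodes, k, n_cliques)`, with attribute `k`.
#' @export
clique_percolation <- function(graph, k = 3L) {
  if (k < 3) stop("k must be >= 3 for clique percolation")
  cl <- enumerate_k_cliques(graph, k)
  if (!length(cl)) {
    out <- list()
    class(out) <- "clique_communities"
    attr(out, "k") <- as.integer(k)
    return(out)
  }
  n <- length(cl)
  uf <- .uf_new(n)
  # two k-cliques share exactly k-1 nodes iff they share some (k-1)-subset
  subkey <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    nodes <- cl[[i]]
    for (drop in seq_len(k)) {
      key <- paste(nodes[-drop], collapse = "\r")
      j <- get0(key, envir = subkey)
      if (is.null(j)) assign(key, i, envir = subkey)
      else {
        ri <- .uf_find(uf, i); rj <- .uf_find(uf, j)
        if (ri != rj) uf[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) .uf_find(uf, i), integer(1))
  comps <- split(seq_len(n), roots)
  comms <- lapply(comps, function(idx)
    list(nodes = sort(unique(unlist(cl[idx]))), k = as.integer(k),
         n_cliques = length(idx)))
  ord <- order(-vapply(comms, function(x) length(x$nodes), integer(1)),
               vapply(comms, function(x) x$nodes[1], character(1)))
  comms <- unname(comms[ord])
  for (i in seq_along(comms)) comms[[i]]$id <- i - 1L
  class(comms) <- "clique_communities"
  attr(comms, "k") <- as.integer(k)
  comms
}

#' @export
print.clique_communities <- function(x, ...) {
  cat("clique_communities: k =", attr(x, "k"), ",", length(x),
      "communities\n")
  for (c in x[seq_len(min(10, length(x)))])
    cat(sprintf("  [%d] %d nodes, %d cliques\n", c$id, length(c$nodes),
                c$n_cliques))
  invisible(x)
}

#' Name a community by its group content and connectivity
#'
#' Name = hyphen-joined sorted distinct group labels of the member nodes,
#' then node count, then induced edge count (e.g. `"VI-16-45"`).
#'
#' @param community One community from [clique_percolation()].
#' @param network A `synteny_network` (or igraph) containing the community.
#' @param groups Optional named vector gene id -> group; defaults to the
#'   network's `group` node attribute.
#' @return The name string.
#' @export
name_community <- function(community, network, groups = NULL) {
  g <- if (inherits(network, "synteny_network")) network$graph else network
  if (is.null(groups)) {
    grp <- igraph::vertex_attr(g, "group")
    groups <- setNames(grp, igraph::V(g)$name)
  }
  labs <- sort(unique(stats::na.omit(unname(groups[community$nodes]))))
  if (!length(labs)) labs <- "unclassified"
  sub <- igraph::induced_subgraph(g, community$nodes)
  paste(c(labs, length(community$nodes), igraph::ecount(sub)),
        collapse = "-")
}

#' Species-composition matrix of communities
#'
#' Counts of community members per species, one column per community (the
#' binary presence heatmap is `matrix > 0`).
#'
#' @param communities A `clique_communities` object.
#' @param network A `synteny_network` with a `species` node attribute.
#' @return Integer matrix, rows = species (sorted), columns = community ids.
#' @export
composition_matrix <- function(communities, network) {
  g <- if (inherits(network, "synteny_network")) network$graph else network
  sp <- igraph::vertex_attr(g, "species")
  if (is.null(sp)) stop("network nodes carry no species attribute")
  species <- setNames(sp, igraph::V(g)$name)
  all_sp <- sort(unique(stats::na.omit(unname(species))))
  m <- matrix(0L, length(all_sp), length(communities),
              dimnames = list(all_sp,
                              vapply(communities, function(c)
                                as.character(c$id), character(1))))
  for (c in communities) {
    tab <- table(stats::na.omit(unname(species[c$nodes])))
    m[names(tab), as.character(c$id)] <- as.integer(tab)
  }
  m
}

#' Fraction of network nodes covered by communities
#'
#' `|distinct nodes in >= 1 community| / |network nodes|`. Also accepts two
#' counts (total nodes, covered nodes) for worked examples.
#'
#' @param communities A `clique_communities` object, or the total node count.
#' @param network A `synteny_network` / igraph, or the covered node count.
#' @param as_percent If TRUE, percentage rounded to 1 decimal.
#' @return Proportion or percentage.
#' @export
community_coverage <- function(communities, network, as_percent = FALSE) {
  if (is.numeric(communities) && length(communities) == 1L &&
      is.numeric(network)) {
    total <- communities; covered <- network
  } else {
    g <- if (inherits(network, "synteny_network")) network$graph else network
    total <- igraph::vcount(g)
    if (total == 0) stop("network is empty")
    covered <- length(unique(unlist(lapply(communities, `[[`, "nodes"))))
  }
  if (total <= 0) stop("network is empty")
  p <- covered / total
  if (as_percent) round(100 * p, 1) else p
}

#' Tabular community summary
#'
#' @param communities A `clique_communities` object.
#' @param network A `synteny_network` with species/group attributes.
#' @return data.frame: one row per community with name, node count, induced
#'   edge count, species count and group set.
#' @export
community_summary <- function(communities, network) {
  g <- if (inherits(network, "synteny_network")) network$graph else network
  sp <- setNames(igraph::vertex_attr(g, "species"), igraph::V(g)$name)
  grp <- setNames(igraph::vertex_attr(g, "group"), igraph::V(g)$name)
  do.call(rbind, lapply(communities, function(c) {
    sub <- igraph::induced_subgraph(g, c$nodes)
    data.frame(community_id = c$id,
               name = name_community(c, network),
               n_nodes = length(c$nodes),
               n_edges = igraph::ecount(sub),
               n_species = length(unique(stats::na.omit(unname(sp[c$nodes])))),
               groups = paste(sort(unique(stats::na.omit(
                 unname(grp[c$nodes])))), collapse = ","),
               stringsAsFactors = FALSE)
  }))
}
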
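# Tree I/O, a neighbor-joining fallback, and reconciliation of synteny
# communities with gene trees: species-overlap duplication calls,
# lineage-specific transposition calls, ancient-tandem flags.

#' Read / write newick trees
#'
#' Thin wrappers over ape with validation; internal-node labels are treated
#' as support values where numeric. `read_newick` reports the character
#' position of the first structural problem for malformed input.
#'
#' @param text A newick string or path to a newick file.
#' @return A `phylo` object.
#' @export
read_newick <- function(text) {
  is_file <- length(text) == 1L && !grepl("[(;]", text) && file.exists(text)
  s <- if (is_file) paste(readLines(text, warn = FALSE), collapse = "") else text
  depth <- 0L
  chars <- strsplit(s, "")[[1]]
  seen_tree <- FALSE
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      seen_tree <- TRUE
      if (depth < 0) stop("newick parse error at position ", i,
                          ": unbalanced ')'")
    }
    if (chars[i] == "," && depth == 0L && seen_tree)
      stop("newick parse error at position ", i,
           ": ',' outside any clade")
  }
  if (depth != 0) stop("newick parse error at position ", length(chars),
                       ": ", depth, " unclosed '('")
  if (!grepl(";", s)) stop("newick parse error at position ", nchar(s),
                           ": missing ';'")
  tr <- tryCatch(ape::read.tree(text = s),
                 error = function(e) stop("newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("newick parse error: unreadable tree")
  tr
}

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @param path Optional output file; if NULL the newick string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(path)
}

#' Pairwise p-distance matrix of an alignment
#'
#' Proportion of differing sites among positions where neither sequence has
#' a gap; the diagonal is 0.
#'
#' @param aln Named character vector of equal-length aligned sequences.
#' @param gap_char Gap character.
#' @return Symmetric numeric matrix.
#' @export
p_distance_matrix <- function(aln, gap_char = "-") {
  aln <- .as_alignment(aln)
  if (length(aln) < 2) stop("need >= 2 sequences")
  m <- do.call(rbind, strsplit(aln, ""))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] != gap_char & m[j, ] != gap_char
    if (!any(ok))
      stop("no comparable sites between ", names(aln)[i], " and ",
           names(aln)[j])
    d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration (ape's implementation) on a symmetric
#' nonnegative distance matrix; taxa are processed in sorted label order so
#' ties resolve deterministically.
#'
#' @param dist Symmetric numeric matrix with row/col names (>= 3 taxa).
#' @return Unrooted `phylo` tree.
#' @export
nj_tree <- function(dist) {
  if (!is.matrix(dist) || nrow(dist) != ncol(dist))
    stop("dist must be a square matrix")
  if (max(abs(dist - t(dist))) > 1e-8) stop("dist must be symmetric")
  if (nrow(dist) < 3) stop("need >= 3 taxa")
  ord <- order(rownames(dist))
  ape::nj(dist[ord, ord])
}

# descendant tip labels for every internal node (rooted representation)
.clade_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  tips <- vector("list", nn)
  for (i in seq_len(ntip)) tips[[i]] <- tree$tip.label[i]
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; c <- edge[e, 2]
    tips[[p]] <- c(tips[[p]], tips[[c]])
  }
  tips
}

#' Test monophyly of a leaf set
#'
#' TRUE iff the leaf set is exactly one side of some bipartition of the
#' (unrooted) tree; on rooted trees this equals a clade test that ignores
#' root placement. Singleton sets and the full leaf set are monophyletic by
#' convention.
#'
#' @param tree A `phylo` object.
#' @param leaves Character vector of leaf labels.
#' @return Logical flag.
#' @export
is_monophyletic <- function(tree, leaves) {
  unknown <- setdiff(leaves, tree$tip.label)
  if (length(unknown)) stop("unknown leaf: ", unknown[1])
  leaves <- unique(leaves)
  all_tips <- tree$tip.label
  if (length(leaves) <= 1L || length(leaves) == length(all_tips))
    return(TRUE)
  tips <- .clade_tips(tree)
  target <- sort(leaves)
  compl <- sort(setdiff(all_tips, leaves))
  for (node in seq_along(tips)) {
    s <- sort(tips[[node]])
    if (identical(s, target) || identical(s, compl)) return(TRUE)
  }
  FALSE
}

# numeric support value of an internal node (NA when absent/non-numeric)
.node_support <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip || is.null(tree$node.label)) return(NA_real_)
  suppressWarnings(as.numeric(tree$node.label[node - ntip]))
}

#' Call duplication nodes by the species-overlap rule
#'
#' An internal node of a rooted gene tree is a duplication iff the species
#' sets of its two child clades intersect. Each call records the shared
#' species and the support values of the node and both children; calls where
#' any available support falls below `min_support` are flagged
#' low-confidence (never dropped). Trees without support values get
#' `low_confidence = NA`.
#'
#' @param tree Rooted `phylo` gene tree (use `outgroup` or
#'   `root = "midpoint"` for unrooted input).
#' @param species_map Named vector: leaf label -> species.
#' @param min_support Support threshold (default 80).
#' @param outgroup Optional leaf label(s) to root by.
#' @param root `"given"` (error on unrooted input) or `"midpoint"`.
#' @return data.frame of duplication calls: node id, shared species count
#'   and list, three supports, low-confidence flag.
#' @export
infer_duplications <- function(tree, species_map, min_support = 80,
                               outgroup = NULL, root = c("given",
                                                         "midpoint")) {
  root <- match.arg(root)
  if (!is.null(outgroup)) {
    og <- intersect(outgroup, tree$tip.label)
    if (!length(og)) stop("outgroup not present in tree")
    tree <- ape::root(tree, outgroup = og[1], resolve.root = TRUE)
  } else if (!ape::is.rooted(tree)) {
    if (root == "midpoint") {
      if (!requireNamespace("phangorn", quietly = TRUE))
        stop("midpoint rooting needs the phangorn package")
      tree <- phangorn::midpoint(tree)
    } else stop("tree is unrooted; supply an outgroup or root='midpoint'")
  }
  miss <- setdiff(tree$tip.label, names(species_map))
  if (length(miss)) stop("leaf missing from species map: ", miss[1])
  ntip <- length(tree$tip.label)
  tips <- .clade_tips(tree)
  calls <- list()
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    if (length(kids) < 2) next
    sets <- lapply(kids, function(k)
      unique(unname(species_map[tips[[k]]])))
    shared <- Reduce(intersect, sets)
    if (!length(shared)) next
    sup <- c(.node_support(tree, node),
             .node_support(tree, kids[1]), .node_support(tree, kids[2]))
    avail <- sup[!is.na(sup)]
    lowconf <- if (!length(avail)) NA else any(avail < min_support)
    calls[[length(calls) + 1L]] <- data.frame(
      kind = "duplication", node = node,
      n_shared_species = length(shared),
      shared_species = paste(sort(shared), collapse = ","),
      support_node = sup[1], support_child1 = sup[2],
      support_child2 = sup[3], low_confidence = lowconf,
      stringsAsFactors = FALSE)
  }
  if (!length(calls))
    return(data.frame(kind = character(0), node = integer(0),
                      n_shared_species = integer(0),
                      shared_species = character(0),
                      support_node = numeric(0), support_child1 = numeric(0),
                      support_child2 = numeric(0),
                      low_confidence = logical(0)))
  do.call(rbind, calls)
}

#' Call lineage-specific transpositions from communities and a gene tree
#'
#' A transposition is called for lineage L when a community of at least
#' `min_community_size` nodes (i) contains genes from >= 2 species that all
#' map to L, (ii) forms a monophyletic set in the group gene tree, and
#' (iii) at least one other community sharing a group label contains genes
#' from outside L (so the restriction is not family-wide). The call scope is
#' the stem lineage of L.
#'
#' @param communities A `clique_communities` object.
#' @param network The `synteny_network` the communities were found in (node
#'   `species` and `group` attributes are used).
#' @param tree A `phylo` gene tree, or a named list of per-group trees.
#' @param lineages data.frame (`species`, `lineage`) or named vector
#'   species -> lineage.
#' @param min_community_size Minimum community size considered (default 4).
#' @return data.frame of transposition calls (possibly 0 rows).
#' @export
call_transpositions <- function(communities, network, tree, lineages,
                                min_community_size = 4L) {
  g <- if (inherits(network, "synteny_network")) network$graph else network
  sp <- setNames(igraph::vertex_attr(g, "species"), igraph::V(g)$name)
  grp <- igraph::vertex_attr(g, "group")
  grp <- if (is.null(grp)) setNames(rep(NA_character_, igraph::vcount(g)),
                                    igraph::V(g)$name)
         else setNames(grp, igraph::V(g)$name)
  if (is.data.frame(lineages))
    lineages <- setNames(lineages$lineage, lineages$species)
  trees <- if (inherits(tree, "phylo")) list(tree) else tree

  comm_species <- lapply(communities, function(c)
    sort(unique(stats::na.omit(unname(sp[c$nodes])))))
  comm_groups <- lapply(communities, function(c)
    sort(unique(stats::na.omit(unname(grp[c$nodes])))))
  comm_lineages <- lapply(comm_species, function(s)
    sort(unique(unname(lineages[s]))))

  calls <- list()
  for (ci in seq_along(communities)) {
    c <- communities[[ci]]
    if (length(c$nodes) < min_community_size) next
    spc <- comm_species[[ci]]
    if (length(spc) < 2) next
    lin <- comm_lineages[[ci]]
    if (length(lin) != 1 || any(is.na(lin))) next
    # (ii) monophyly in the group tree; truncated syntelogs are kept out of
    # phylogenies, so the tree test applies to the member-status genes
    status <- igraph::vertex_attr(g, "status")
    tree_nodes <- if (is.null(status)) c$nodes else
      c$nodes[setNames(status, igraph::V(g)$name)[c$nodes] != "truncated"]
    tr <- NULL
    for (t in trees) if (all(tree_nodes %in% t$tip.label)) { tr <- t; break }
    if (is.null(tr)) {
      warning("community ", c$id, " skipped: genes absent from gene tree")
      next
    }
    if (!is_monophyletic(tr, tree_nodes)) next
    # (iii) a sibling community in the same group reaching outside L
    sib <- FALSE
    for (cj in seq_along(communities)) {
      if (cj == ci) next
      if (!length(intersect(comm_groups[[ci]], comm_groups[[cj]]))) next
      if (any(unname(lineages[comm_species[[cj]]]) != lin, na.rm = TRUE)) {
        sib <- TRUE
        break
      }
    }
    if (!sib) next
    calls[[length(calls) + 1L]] <- data.frame(
      kind = "transposition", lineage = lin, community_id = c$id,
      n_nodes = length(c$nodes), n_species = length(spc),
      species = paste(spc, collapse = ","),
      groups = paste(comm_groups[[ci]], collapse = ","),
      monophyletic = TRUE, scope = paste0("stem:", lin),
      stringsAsFactors = FALSE)
  }
  if (!length(calls))
    return(data.frame(kind = character(0), lineage = character(0),
                      community_id = integer(0), n_nodes = integer(0),
                      n_species = integer(0), species = character(0),
                      groups = character(0), monophyletic = logical(0),
                      scope = character(0)))
  do.call(rbind, calls)
}

#' Flag communities carrying several groups as ancient tandem duplications
#'
#' Communities whose members span >= 2 distinct group labels are flagged
#' `ancient_tandem` (the reciprocal-loss signature: an ancient tandem pair
#' whose two members were differentially lost leaves cross-group syntenic
#' connections). The cross-group edge list is attached when the network is
#' supplied.
#'
#' @param communities A `clique_communities` object.
#' @param groups Named vector gene id -> group label.
#' @param network Optional `synteny_network` used to list cross-group edges.
#' @return data.frame of flags (possibly 0 rows) with the group multiset and
#'   cross-group edge list per flagged community.
#' @export
flag_ancient_tandem <- function(communities, groups, network = NULL) {
  calls <- list()
  for (c in communities) {
    gl <- stats::na.omit(unname(groups[c$nodes]))
    tab <- table(gl)
    if (length(tab) < 2) next
    xedges <- NA_character_
    if (!is.null(network)) {
      g <- if (inherits(network, "synteny_network")) network$graph
           else network
      sub <- igraph::induced_subgraph(g, intersect(c$nodes,
                                                   igraph::V(g)$name))
      el <- igraph::as_edgelist(sub)
      if (nrow(el)) {
        cross <- groups[el[, 1]] != groups[el[, 2]] &
          !is.na(groups[el[, 1]]) & !is.na(groups[el[, 2]])
        xedges <- paste(paste0(el[cross, 1], "~", el[cross, 2]),
                        collapse = ",")
      }
    }
    calls[[length(calls) + 1L]] <- data.frame(
      kind = "ancient_tandem", community_id = c$id,
      n_nodes = length(c$nodes),
      group_multiset = paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                             collapse = ","),
      cross_group_edges = xedges, stringsAsFactors = FALSE)
  }
  if (!length(calls))
    return(data.frame(kind = character(0), community_id = integer(0),
                      n_nodes = integer(0), group_multiset = character(0),
                      cross_group_edges = character(0)))
  do.call(rbind, calls)
}
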
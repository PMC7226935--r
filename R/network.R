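# Family-anchored synteny network: anchor pairs between family genes become
# undirected edges; truncated syntelogs are detected from anchors linking
# partial-domain genes to members.

#' Build the family synteny network from collinear blocks
#'
#' Every anchor pair whose two genes are both in `members` becomes an edge;
#' parallel anchors from different blocks collapse to a single edge carrying
#' the block list. Nodes are the genes incident to at least one edge;
#' family members with no syntenic partner are reported separately.
#'
#' @param blocks List of `collinear_block` objects.
#' @param members Character vector of family gene ids (may include
#'   truncated syntelogs).
#' @param gene_info Optional data.frame (`gene_id`, `species`, `group`,
#'   `status`) attached as node attributes.
#' @return A `synteny_network`: list with `graph` (igraph, undirected,
#'   simple), `non_syntenic` (members without an edge), `n_anchor_pairs`
#'   (raw member-member anchor count before collapsing).
#' @export
build_family_synteny_network <- function(blocks, members, gene_info = NULL) {
  at <- anchor_table(blocks)
  if (nrow(at)) {
    keep <- at$q_gene %in% members & at$s_gene %in% members
    at <- at[keep, , drop = FALSE]
  }
  if (!nrow(at)) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    net <- list(graph = g, non_syntenic = sort(members), n_anchor_pairs = 0L)
    class(net) <- "synteny_network"
    return(net)
  }
  ends <- data.frame(
    a = pmin(at$q_gene, at$s_gene), b = pmax(at$q_gene, at$s_gene),
    block_id = at$block_id, stringsAsFactors = FALSE)
  ends <- ends[ends$a != ends$b, , drop = FALSE]
  n_raw <- nrow(ends)
  key <- paste(ends$a, ends$b, sep = "\r")
  blocks_per_edge <- tapply(ends$block_id, key,
                            function(x) paste(sort(unique(x)), collapse = ","))
  first <- !duplicated(key)
  edges <- ends[first, c("a", "b")]
  edges$block_ids <- unname(blocks_per_edge[key[first]])
  edges <- edges[order(edges$a, edges$b), ]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  if (!is.null(gene_info)) {
    idx <- match(igraph::V(g)$name, gene_info$gene_id)
    for (col in intersect(c("species", "group", "status"),
                          names(gene_info)))
      g <- igraph::set_vertex_attr(g, col, value = gene_info[[col]][idx])
  }
  net <- list(graph = g,
              non_syntenic = sort(setdiff(members, igraph::V(g)$name)),
              n_anchor_pairs = n_raw)
  class(net) <- "synteny_network"
  net
}

#' @export
print.synteny_network <- function(x, ...) {
  cat("synteny_network:", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges (", x$n_anchor_pairs,
      "anchor pairs ),", length(x$non_syntenic), "non-syntenic members\n")
  invisible(x)
}

#' Detect truncated syntelogs
#'
#' Partial-domain genes that are anchor-paired with a family member in any
#' collinear block are flagged `truncated`; they join the network (but are
#' kept out of phylogenies) and can be classified by
#' [classify_by_reference()].
#'
#' @param blocks List of `collinear_block` objects.
#' @param members Family member gene ids.
#' @param partial Partial-domain gene ids (from
#'   [identify_family_members()]).
#' @return data.frame `gene_id`, `status` (`"truncated"`), `partner_count`
#'   (distinct member partners).
#' @export
detect_truncated_syntelogs <- function(blocks, members, partial) {
  empty <- data.frame(gene_id = character(0), status = character(0),
                      partner_count = integer(0))
  at <- anchor_table(blocks)
  if (!nrow(at) || !length(partial)) return(empty)
  fwd <- at[at$q_gene %in% partial & at$s_gene %in% members,
            c("q_gene", "s_gene")]
  rev <- at[at$s_gene %in% partial & at$q_gene %in% members,
            c("s_gene", "q_gene")]
  names(fwd) <- names(rev) <- c("gene", "partner")
  pairs <- unique(rbind(fwd, rev))
  if (!nrow(pairs)) return(empty)
  cnt <- tapply(pairs$partner, pairs$gene, function(x) length(unique(x)))
  data.frame(gene_id = sort(names(cnt)), status = "truncated",
             partner_count = as.integer(cnt[sort(names(cnt))]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fraction of family members with syntenic support
#'
#' `|syntenic members| / |members|`. Accepts either a member set plus a
#' network, or two counts (total members, syntenic members) for worked
#' examples at printed scale.
#'
#' @param members Character vector of member gene ids, or a single count.
#' @param network A `synteny_network`, or the syntenic-member count.
#' @param as_percent If TRUE, return a percentage rounded to 1 decimal (the
#'   reporting convention); otherwise the raw proportion.
#' @return Proportion or percentage.
#' @export
syntenic_fraction <- function(members, network, as_percent = FALSE) {
  if (is.numeric(members) && length(members) == 1L && is.numeric(network)) {
    total <- members; synt <- network
  } else {
    if (!length(members)) stop("members must be nonempty")
    total <- length(members)
    synt <- sum(members %in% igraph::V(network$graph)$name)
  }
  if (total <= 0) stop("members must be nonempty")
  p <- synt / total
  if (as_percent) round(100 * p, 1) else p
}

#' Summarize intra- and inter-group connectivity
#'
#' @param network A `synteny_network` whose nodes carry a `group` attribute
#'   (or supply `groups`).
#' @param groups Optional named vector gene id -> group label; missing genes
#'   count as `"unclassified"`.
#' @return list with `matrix` (symmetric group-pair edge counts, including
#'   an `unclassified` band) and `inter_group_total` (edges whose two
#'   endpoints carry distinct known groups; unclassified endpoints excluded).
#' @export
intergroup_edge_summary <- function(network, groups = NULL) {
  g <- network$graph
  if (is.null(groups)) {
    grp <- igraph::vertex_attr(g, "group")
    if (is.null(grp)) stop("network nodes carry no group attribute")
    groups <- setNames(grp, igraph::V(g)$name)
  }
  groups[is.na(groups)] <- "unclassified"
  el <- igraph::as_edgelist(g)
  ga <- ifelse(el[, 1] %in% names(groups), groups[el[, 1]], "unclassified")
  gb <- ifelse(el[, 2] %in% names(groups), groups[el[, 2]], "unclassified")
  labs <- sort(unique(c(ga, gb, setdiff(unique(groups), NA))))
  m <- matrix(0L, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_along(ga)) {
    x <- ga[i]; y <- gb[i]
    m[x, y] <- m[x, y] + 1L
    if (x != y) m[y, x] <- m[y, x] + 1L
  }
  known <- ga != "unclassified" & gb != "unclassified"
  list(matrix = m, inter_group_total = sum(known & ga != gb))
}

#' Export / import the synteny network
#'
#' Edge-list TSV (gene pair, species, groups, block ids) or GraphML with all
#' node and edge attributes; both round-trip losslessly.
#'
#' @param network A `synteny_network`.
#' @param path Output file.
#' @param format `"tsv"` or `"graphml"`.
#' @export
export_network <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  g <- network$graph
  if (igraph::vcount(g) == 0) stop("network is empty")
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(g)
  va <- function(attr, ids) {
    v <- igraph::vertex_attr(g, attr)
    if (is.null(v)) rep(NA_character_, length(ids))
    else v[match(ids, igraph::V(g)$name)]
  }
  d <- data.frame(gene_a = el[, 1], gene_b = el[, 2],
                  species_a = va("species", el[, 1]),
                  species_b = va("species", el[, 2]),
                  group_a = va("group", el[, 1]),
                  group_b = va("group", el[, 2]),
                  block_ids = igraph::edge_attr(g, "block_ids"),
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
  } else {
    d <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(
      d[, c("gene_a", "gene_b", "block_ids")], directed = FALSE)
    for (side in c("a", "b")) {
      ids <- d[[paste0("gene_", side)]]
      for (attr in c("species", "group")) {
        v <- d[[paste0(attr, "_", side)]]
        idx <- match(ids, igraph::V(g)$name)
        cur <- igraph::vertex_attr(g, attr)
        if (is.null(cur)) cur <- rep(NA_character_, igraph::vcount(g))
        cur[idx] <- as.character(v)
        g <- igraph::set_vertex_attr(g, attr, value = cur)
      }
    }
  }
  net <- list(graph = g, non_syntenic = character(0),
              n_anchor_pairs = NA_integer_)
  class(net) <- "synteny_network"
  net
}
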
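# Tree I/O, distances, NJ, monophyly, and the event-calling rules.

test_that("newick round-trips topology, lengths and supports", {
  tr <- read_newick("((a,b),(c,d));")
  expect_equal(length(tr$tip.label), 4)
  expect_equal(tr$Nnode, 3)
  s <- write_newick(tr)
  expect_identical(write_newick(read_newick(s)), s)
  trs <- read_newick("((a,b)95,(c,d)80);")
  expect_true(all(c("95", "80") %in% trs$node.label))
  expect_identical(write_newick(trs), "((a,b)95,(c,d)80);")
  wl <- read_newick("((a:1.5,b:2):0.5,c:3);")
  expect_equal(sort(wl$edge.length), c(0.5, 1.5, 2, 3))
  expect_error(read_newick("((a,b),(c,d);"), "position")
  expect_error(read_newick("((a,b)),c;"), "position 8")
  expect_error(read_newick("((a,b),(c,d))"), "';'")
})

test_that("p-distance ignores gapped sites and is symmetric with zero diagonal", {
  expect_equal(p_distance_matrix(c(a = "AAAA", b = "AAAA"))["a", "b"], 0)
  expect_equal(p_distance_matrix(c(a = "AAAA", b = "AAAT"))["a", "b"], 0.25)
  d <- p_distance_matrix(c(a = "ACGT-A", b = "AC-TTA", c = "TCGTTA"))
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_equal(d["a", "b"], 0)        # comparable sites: A,C,T,A all equal
  expect_equal(d["a", "c"], 1 / 5)
  expect_error(p_distance_matrix(c(a = "--AA", b = "AA--")), "comparable")
  expect_error(p_distance_matrix(c(a = "ACGT")), ">= 2")
})

test_that("NJ recovers additive trees and the 3-taxon closed form", {
  d3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- nj_tree(d3)
  # closed form: x = (dab+dac-dbc)/2 etc.
  bl <- setNames(tr3$edge.length, tr3$tip.label[tr3$edge[, 2]])
  expect_equal(unname(bl["a"]), 1)
  expect_equal(unname(bl["b"]), 2)
  expect_equal(unname(bl["c"]), 4)
  # additive matrices from random trees: topology recovered exactly
  for (s in 1:8) {
    set.seed(s)
    n <- if (s <= 4) 4 else 6
    tr <- ape::rtree(n, tip.label = letters[1:n])
    tr$edge.length <- rep(1, nrow(tr$edge))
    d <- ape::cophenetic.phylo(tr)
    got <- nj_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(got)), 0,
                 ignore_attr = TRUE, info = paste("seed", s))
  }
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|taxa")
  asym <- matrix(c(0, 1, 3, 2, 0, 1, 3, 1, 0), 3)
  expect_error(nj_tree(asym), "symmetric")
})

test_that("monophyly equals the bipartition oracle on random trees", {
  tr <- read_newick("((a,b),(c,d));")
  expect_true(is_monophyletic(tr, c("a", "b")))
  expect_false(is_monophyletic(tr, c("a", "c")))
  expect_error(is_monophyletic(tr, c("a", "zz")), "unknown leaf")
  for (s in 1:6) {
    set.seed(s)
    n <- sample(8:12, 1)
    tree <- ape::rtree(n, tip.label = paste0("t", 1:n))
    for (rep in 1:8) {
      leaves <- sample(tree$tip.label, sample(2:(n - 1), 1))
      expect_equal(is_monophyletic(tree, leaves),
                   brute_monophyletic(tree, leaves),
                   info = paste("seed", s, paste(leaves, collapse = ",")))
    }
  }
  # agreement with the field-standard clade test on rooted trees
  for (s in 1:4) {
    set.seed(100 + s)
    tree <- ape::rtree(8, tip.label = paste0("t", 1:8))
    leaves <- sample(tree$tip.label, 3)
    expect_equal(is_monophyletic(tree, leaves),
                 ape::is.monophyletic(tree, leaves) ||
                   ape::is.monophyletic(tree,
                                        setdiff(tree$tip.label, leaves)))
  }
})

test_that("species-overlap rule calls duplications with support bookkeeping", {
  tr <- read_newick("((A1,B1)90,(A2,B2)85)99;")
  smap <- c(A1 = "A", B1 = "B", A2 = "A", B2 = "B")
  d <- infer_duplications(tr, smap)
  expect_equal(nrow(d), 1)
  expect_equal(d$shared_species, "A,B")
  expect_equal(d$n_shared_species, 2)
  expect_false(d$low_confidence)   # 99, 90, 85 all >= 80
  d2 <- infer_duplications(tr, smap, min_support = 95)
  expect_true(d2$low_confidence)
  # disjoint child species sets: no duplication
  tr2 <- read_newick("((A1,B1),(C1,D1));")
  expect_equal(nrow(infer_duplications(
    tr2, c(A1 = "A", B1 = "B", C1 = "C", D1 = "D"))), 0)
  # unrooted tree without a rooting directive errors
  utr <- ape::unroot(read_newick("((A1,B1),(A2,B2),(A3,B3));"))
  expect_error(infer_duplications(utr, c(A1 = "A", B1 = "B", A2 = "A",
                                         B2 = "B", A3 = "A", B3 = "B")),
               "unrooted")
  # support-free trees get low_confidence = NA, never TRUE
  tr3 <- read_newick("((A1,B1),(A2,B2));")
  expect_true(is.na(infer_duplications(tr3, smap)$low_confidence))
})

test_that("transposition rule needs lineage purity, monophyly and a sibling", {
  # two K4 communities; community 0 pure lineage L and monophyletic,
  # community 1 spans lineages M and N
  g <- igraph::make_full_graph(4) + igraph::make_full_graph(4)
  g <- igraph::set_vertex_attr(g, "name", value = paste0("g", 1:8))
  g <- igraph::set_vertex_attr(g, "species",
                               value = c("sp1", "sp1", "sp2", "sp2",
                                         "sp3", "sp3", "sp4", "sp4"))
  g <- igraph::set_vertex_attr(g, "group", value = rep("VI", 8))
  g <- igraph::set_vertex_attr(g, "status", value = rep("member", 8))
  net <- list(graph = g, non_syntenic = character(0), n_anchor_pairs = 0L)
  class(net) <- "synteny_network"
  comms <- clique_percolation(net, 3)
  tree <- read_newick("(((g1,g2),(g3,g4)),((g5,g6),(g7,g8)));")
  lin <- c(sp1 = "L", sp2 = "L", sp3 = "M", sp4 = "N")
  calls <- call_transpositions(comms, net, tree, lin)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$lineage, "L")
  expect_equal(calls$n_nodes, 4)
  # family-wide restriction: if the sibling community is also pure L,
  # nothing distinguishes a transposition
  lin2 <- c(sp1 = "L", sp2 = "L", sp3 = "L", sp4 = "L")
  expect_equal(nrow(call_transpositions(comms, net, tree, lin2)), 0)
  # non-monophyletic community is not called
  tree2 <- read_newick("(((g1,g2),(g5,g6)),((g3,g4),(g7,g8)));")
  expect_equal(nrow(call_transpositions(comms, net, tree2, lin)), 0)
  # genes missing from the tree: community skipped with a warning
  tree3 <- read_newick("((g1,g2),(g5,(g6,(g7,g8))));")
  expect_warning(call_transpositions(comms, net, tree3, lin), "skipped")
})

test_that("multi-group communities are flagged as ancient tandem signatures", {
  g <- igraph::make_full_graph(3) + igraph::make_full_graph(3)
  g <- igraph::set_vertex_attr(g, "name", value = paste0("g", 1:6))
  comms <- clique_percolation(g, 3)
  groups <- c(g1 = "IV", g2 = "VI", g3 = "VI",
              g4 = "I", g5 = "I", g6 = "I")
  out <- flag_ancient_tandem(comms, groups)
  expect_equal(nrow(out), 1)
  expect_match(out$group_multiset, "IV:1")
  expect_match(out$group_multiset, "VI:2")
  # brute-force recount under random relabeling
  set.seed(3)
  for (rep in 1:5) {
    grp <- setNames(sample(c("I", "VI"), 6, replace = TRUE),
                    paste0("g", 1:6))
    flagged <- flag_ancient_tandem(comms, grp)
    manual <- sum(vapply(comms, function(c)
      length(unique(grp[c$nodes])) >= 2, logical(1)))
    expect_equal(nrow(flagged), manual)
  }
  # cross-group edges are listed when the network is supplied
  g2 <- igraph::set_vertex_attr(g, "group", value = unname(groups))
  net <- list(graph = g2, non_syntenic = character(0), n_anchor_pairs = 0L)
  class(net) <- "synteny_network"
  out2 <- flag_ancient_tandem(comms, groups, net)
  expect_match(out2$cross_group_edges, "g1~g2|g2~g1")
})
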
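# Synteny network: edge construction from member anchors, truncated-syntelog
# detection, fraction/connectivity summaries, lossless export.

# a minimal hand-built block
toy_block <- function(anchors, id = 1L) {
  b <- list(block_id = id, genomes = c("A", "B"), chroms = c("c1", "c1"),
            orientation = 1L, anchors = anchors, score = 100,
            n_anchors = nrow(anchors))
  class(b) <- "collinear_block"
  b
}

test_that("only member-member anchor pairs become edges", {
  anchors <- data.frame(
    q_gene = paste0("a", 1:5), s_gene = paste0("b", 1:5),
    q_rank = 1:5, s_rank = 1:5, stringsAsFactors = FALSE)
  members <- c("a3", "b3")   # one member pair among five anchors
  net <- build_family_synteny_network(list(toy_block(anchors)), members)
  expect_equal(igraph::vcount(net$graph), 2)
  expect_equal(igraph::ecount(net$graph), 1)
  expect_length(net$non_syntenic, 0)
  # no member anchors: empty network, every member non-syntenic
  net0 <- build_family_synteny_network(list(toy_block(anchors)),
                                       c("x1", "x2"))
  expect_equal(igraph::vcount(net0$graph), 0)
  expect_setequal(net0$non_syntenic, c("x1", "x2"))
})

test_that("parallel anchors collapse to one edge carrying the block list", {
  anchors <- data.frame(q_gene = "a1", s_gene = "b1", q_rank = 1, s_rank = 1)
  blocks <- list(toy_block(anchors, 1L), toy_block(anchors, 7L))
  net <- build_family_synteny_network(blocks, c("a1", "b1"))
  expect_equal(igraph::ecount(net$graph), 1)
  expect_equal(igraph::E(net$graph)$block_ids, "1,7")
  expect_equal(net$n_anchor_pairs, 2)
})

test_that("WGD duplicate pairs inside blocks are all recovered as edges", {
  cfg <- planted_wgd_config(seed = 2, out_dir = tempfile())
  tree <- scenario_species_tree()
  gs <- evolve_genomes(tree, cfg$sim, cfg$forced_events)
  loci <- gene_loci(gs)
  hits <- filter_top_hits(emit_homology_hits(gs), 5)
  blocks <- chain_collinear_blocks(hits, loci)
  fam <- identify_family_members(emit_domain_table(gs))
  net <- build_family_synteny_network(blocks, fam$members)
  g <- net$graph
  # ground truth: for every family orthogroup, the two within-genome WGD
  # copies in each clade species must be connected when both are members
  genes <- gs$genes[gs$genes$extant & gs$genes$family, ]
  for (sp in c("s3", "s4", "s5")) {
    bysp <- genes[genes$species == sp, ]
    for (o in split(bysp$gene_id, bysp$orthogroup)) {
      o <- intersect(o, fam$members)
      if (length(o) == 2)
        expect_true(igraph::are_adjacent(g, o[1], o[2]),
                    info = paste(sp, paste(o, collapse = "~")))
    }
  }
  # conservation: syntenic + non-syntenic = all members
  expect_equal(igraph::vcount(g) + length(net$non_syntenic),
               length(fam$members))
})

test_that("partial-domain genes anchored to members are flagged truncated", {
  anchors <- data.frame(
    q_gene = c("m1", "p1", "x1"), s_gene = c("m2", "m3", "x2"),
    q_rank = 1:3, s_rank = 1:3, stringsAsFactors = FALSE)
  blocks <- list(toy_block(anchors))
  out <- detect_truncated_syntelogs(blocks, c("m1", "m2", "m3"),
                                    c("p1", "p9"))
  expect_equal(out$gene_id, "p1")
  expect_equal(out$status, "truncated")
  expect_equal(out$partner_count, 1L)
  # in the noise-free simulation every truncated gene is recovered
  cfg <- null_config(seed = 4, out_dir = tempfile())
  tree <- scenario_species_tree()
  gs <- evolve_genomes(tree, cfg$sim)
  fam <- identify_family_members(emit_domain_table(gs))
  blocks2 <- chain_collinear_blocks(
    filter_top_hits(emit_homology_hits(gs), 5), gene_loci(gs))
  det <- detect_truncated_syntelogs(blocks2, fam$members, fam$partial)
  truth <- gs$genes$gene_id[gs$genes$extant & gs$genes$truncated]
  expect_setequal(det$gene_id, truth)
})

test_that("syntenic fraction reproduces printed ratios and edge cases", {
  expect_equal(syntenic_fraction(1227, 1096, as_percent = TRUE), 89.3)
  anchors <- data.frame(q_gene = "a", s_gene = "b", q_rank = 1, s_rank = 1)
  net <- build_family_synteny_network(list(toy_block(anchors)), c("a", "b"))
  expect_equal(syntenic_fraction(c("a", "b"), net, as_percent = TRUE), 100)
  expect_equal(syntenic_fraction(c("z1", "z2"),
                                 build_family_synteny_network(list(),
                                                              c("z1", "z2")),
                                 as_percent = TRUE), 0)
  expect_error(syntenic_fraction(character(0), net), "nonempty")
})

test_that("inter-group summary matches a brute-force recount under shuffling", {
  set.seed(7)
  g <- random_named_graph(20, 0.25, seed = 7)
  nodes <- igraph::V(g)$name
  for (rep in 1:3) {
    grp <- setNames(sample(c("I", "IV", "VI"), 20, replace = TRUE), nodes)
    net <- list(graph = g, non_syntenic = character(0),
                n_anchor_pairs = 0L)
    class(net) <- "synteny_network"
    out <- intergroup_edge_summary(net, grp)
    el <- igraph::as_edgelist(g)
    manual <- sum(grp[el[, 1]] != grp[el[, 2]])
    expect_equal(out$inter_group_total, manual)
    expect_true(isSymmetric(out$matrix))
    expect_equal(sum(out$matrix[upper.tri(out$matrix)]) +
                 sum(diag(out$matrix)), nrow(el))
  }
  # a single cross-group edge lands in the right matrix cell
  g2 <- igraph::make_graph(~ amb - os)
  net2 <- list(graph = g2, non_syntenic = character(0), n_anchor_pairs = 0L)
  class(net2) <- "synteny_network"
  m <- intergroup_edge_summary(net2, c(amb = "IV", os = "VI"))$matrix
  expect_equal(m["IV", "VI"], 1L)
})

test_that("edge-list and GraphML exports round-trip the attributed graph", {
  anchors <- data.frame(q_gene = c("a1", "a2"), s_gene = c("b1", "b2"),
                        q_rank = 1:2, s_rank = 1:2)
  info <- data.frame(gene_id = c("a1", "a2", "b1", "b2"),
                     species = c("A", "A", "B", "B"),
                     group = c("I", "II", "I", "II"),
                     status = "member")
  net <- build_family_synteny_network(list(toy_block(anchors)),
                                      info$gene_id, info)
  tsv <- tempfile(fileext = ".tsv")
  export_network(net, tsv, "tsv")
  expect_equal(length(readLines(tsv)), 1 + igraph::ecount(net$graph))
  back <- import_network(tsv, "tsv")
  expect_true(igraph::isomorphic(net$graph, back$graph))
  expect_setequal(igraph::V(back$graph)$name, igraph::V(net$graph)$name)
  expect_equal(
    setNames(igraph::V(back$graph)$species, igraph::V(back$graph)$name)[
      igraph::V(net$graph)$name],
    setNames(igraph::V(net$graph)$species, igraph::V(net$graph)$name))
  gml <- tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  back2 <- import_network(gml, "graphml")
  expect_true(igraph::isomorphic(net$graph, back2$graph))
  expect_setequal(igraph::V(back2$graph)$species,
                  igraph::V(net$graph)$species)
  expect_error(export_network(net, tempfile(), "dot"), "arg")
  empty <- build_family_synteny_network(list(), "z")
  expect_error(export_network(empty, tempfile(), "tsv"), "empty")
})
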
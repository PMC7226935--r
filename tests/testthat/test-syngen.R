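# Genome-evolution simulator: tree simulation, event mechanics, ground-truth
# bookkeeping, emitted artifact structure, determinism.

quiet_params <- function(seed = 1, truncated_fraction = 0, ...)
  sim_params(rate_tandem = 0, rate_transposition = 0, rate_loss = 0,
             truncated_fraction = truncated_fraction, seed = seed, ...)

test_that("species tree simulation is valid, seeded and sized correctly", {
  expect_error(simulate_species_tree(1), "n_species")
  cherry <- simulate_species_tree(2, seed = 1)
  expect_equal(length(cherry$tip.label), 2)
  expect_equal(cherry$Nnode, 1)
  expect_identical(ape::write.tree(simulate_species_tree(8, seed = 7)),
                   ape::write.tree(simulate_species_tree(8, seed = 7)))
  for (s in c(7, 8)) {
    tr <- simulate_species_tree(8, seed = s)
    expect_equal(length(tr$tip.label), 8)
    expect_equal(tr$Nnode, 7)
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("with all rates zero, extant genomes equal the ancestor", {
  tr <- scenario_species_tree()
  gs <- evolve_genomes(tr, quiet_params())
  expect_equal(nrow(gs$events), 0)
  anc_og_order <- split(sprintf("og%04d", 1:200),
                        sort(rep_len(1:4, 200)))
  og <- setNames(gs$genes$orthogroup, gs$genes$gene_id)
  for (sp in names(gs$genomes)) {
    gn <- gs$genomes[[sp]]
    expect_equal(length(gn), 4)
    for (i in seq_along(gn))
      expect_equal(unname(og[gn[[i]]]), anc_og_order[[i]])
  }
})

test_that("a planted transposition changes flanking genes only in the clade", {
  tr <- scenario_species_tree()
  gs <- evolve_genomes(tr, quiet_params(),
                       list(list(branch = c("s3", "s4", "s5"),
                                 kind = "transposition")))
  ev <- gs$events
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "transposition")
  og <- setNames(gs$genes$orthogroup, gs$genes$gene_id)
  moved_og <- unname(og[ev$source_gene])
  flanks <- function(sp) {
    gn <- gs$genomes[[sp]]
    for (ch in names(gn)) {
      v <- gn[[ch]]
      i <- which(og[v] == moved_og)
      if (length(i))
        return(sort(unname(og[v[c(max(i - 1, 1), min(i + 1, length(v)))]])))
    }
    NULL
  }
  out_fl <- flanks("s1")
  for (sp in c("s3", "s4", "s5"))
    expect_false(identical(flanks(sp), out_fl))
  for (sp in c("s2", "s6", "s7", "s8"))
    expect_identical(flanks(sp), out_fl)
})

test_that("a terminal-branch WGD exactly doubles that genome", {
  tr <- scenario_species_tree()
  gs <- evolve_genomes(tr, quiet_params(),
                       list(list(branch = "s4", kind = "WGD")))
  counts <- vapply(gs$genomes, function(g) length(unlist(g)), integer(1))
  expect_equal(unname(counts[["s4"]]), 400)
  expect_true(all(counts[names(counts) != "s4"] == 200))
})

test_that("gene counts balance the event ledger on every root-to-tip path", {
  tr <- scenario_species_tree()
  p <- sim_params(rate_tandem = 0.3, rate_loss = 0.5,
                  rate_transposition = 0.2, truncated_fraction = 0,
                  seed = 11)
  gs <- evolve_genomes(tr, p)
  expect_gt(nrow(gs$events), 0)
  ntip <- length(tr$tip.label)
  parent_of <- setNames(tr$edge[, 1], tr$edge[, 2])
  for (tip in seq_len(ntip)) {
    path <- tip
    while (!is.na(parent_of[as.character(path[1])]))
      path <- c(parent_of[[as.character(path[1])]], path)
    ev <- gs$events[gs$events$branch %in% path, ]
    gains <- sum(ev$n_genes[ev$kind %in% c("WGD", "tandem")])
    losses <- sum(ev$kind == "loss")
    expect_equal(length(unlist(gs$genomes[[tr$tip.label[tip]]])),
                 200 + gains - losses)
  }
})

test_that("noise-free hits equal the co-orthogroup pair set, partitioned per comparison", {
  tr3 <- simulate_species_tree(3, seed = 2)
  gs <- evolve_genomes(tr3, quiet_params())
  hits <- emit_homology_hits(gs)
  # unordered genome pairs plus self-comparisons: 3*2/2 + 3 = 6
  expect_equal(length(split_hits_by_comparison(hits)), 6)
  og <- setNames(gs$genes$orthogroup, gs$genes$gene_id)
  expect_true(all(og[hits$query] == og[hits$subject]))
  # every ordered co-orthogroup pair (incl. self) appears exactly once
  ext <- gs$genes[gs$genes$extant, ]
  expect_equal(nrow(hits), sum(table(ext$orthogroup)^2))
  expect_false(any(duplicated(hits[, c("query", "subject")])))
})

test_that("with only the spurious channel active, every hit is cross-orthogroup", {
  tr3 <- simulate_species_tree(3, seed = 2)
  gs <- evolve_genomes(tr3, quiet_params(spurious_hit_rate = 1))
  hits <- emit_homology_hits(gs, suppress_true = TRUE)
  expect_gt(nrow(hits), 0)
  og <- setNames(gs$genes$orthogroup, gs$genes$gene_id)
  expect_true(all(og[hits$query] != og[hits$subject]))
})

test_that("domain table encodes member and truncated status", {
  tr <- scenario_species_tree()
  gs <- evolve_genomes(tr, quiet_params(truncated_fraction = 0.2))
  dt <- emit_domain_table(gs)
  genes <- gs$genes[gs$genes$extant, ]
  fam <- genes[genes$family, ]
  expect_setequal(dt$gene_id, fam$gene_id)
  n_dom <- lengths(strsplit(dt$domains, ","))
  tr_flag <- setNames(fam$truncated, fam$gene_id)[dt$gene_id]
  expect_true(all(n_dom[tr_flag] == 1))
  expect_true(all(n_dom[!tr_flag] == 2))
  expect_true(all(grepl("PF02362|PF06507", dt$domains)))
  # zero truncation: every row lists both domains
  gs0 <- evolve_genomes(tr, quiet_params())
  expect_true(all(emit_domain_table(gs0)$domains == "PF02362,PF06507"))
})

test_that("sequences are identical without substitution and track path length with it", {
  tr <- scenario_species_tree()
  gs0 <- evolve_genomes(tr, quiet_params(subst_rate = 0))
  seqs0 <- emit_sequences(gs0)
  og <- setNames(gs0$genes$orthogroup, gs0$genes$gene_id)
  for (o in split(names(seqs0), og[names(seqs0)]))
    expect_equal(length(unique(seqs0[o])), 1)
  # p-distance grows with species-tree path length (pooled replicates)
  dmat <- ape::cophenetic.phylo(tr)
  pd <- tp <- numeric(0)
  for (s in 1:5) {
    gs <- evolve_genomes(tr, quiet_params(seed = s, subst_rate = 0.02,
                                          family_fraction = 0.03))
    seqs <- emit_sequences(gs)
    ogx <- setNames(gs$genes$orthogroup, gs$genes$gene_id)
    spx <- setNames(gs$genes$species, gs$genes$gene_id)
    for (o in split(names(seqs), ogx[names(seqs)])) {
      d <- p_distance_matrix(seqs[o])
      for (i in seq_along(o)[-1]) for (j in seq_len(i - 1)) {
        pd <- c(pd, d[i, j])
        tp <- c(tp, dmat[spx[[o[i]]], spx[[o[j]]]])
      }
    }
  }
  expect_gt(cor(pd, tp, method = "spearman"), 0)
})

test_that("identical params and seed reproduce every artifact byte-for-byte", {
  tr <- scenario_species_tree()
  p <- sim_params(rate_tandem = 0.2, rate_loss = 0.2, seed = 9)
  a <- evolve_genomes(tr, p)
  b <- evolve_genomes(tr, p)
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$events, b$events)
  expect_identical(emit_sequences(a), emit_sequences(b))
  expect_identical(emit_domain_table(a), emit_domain_table(b))
  fa <- tempfile(fileext = ".fasta")
  fb <- tempfile(fileext = ".fasta")
  write_fasta(emit_sequences(a), fa)
  write_fasta(emit_sequences(b), fb)
  expect_identical(readLines(fa), readLines(fb))
})
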
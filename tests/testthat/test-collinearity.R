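# Collinearity: comparison bookkeeping, top-hit filtering, tandem collapsing,
# and the chaining DP against exhaustive search.

make_loci <- function(ranks_by_chrom) {
  do.call(rbind, lapply(names(ranks_by_chrom), function(key) {
    parts <- strsplit(key, ":")[[1]]
    data.frame(gene_id = ranks_by_chrom[[key]], species = parts[1],
               chromosome = parts[2],
               rank = seq_along(ranks_by_chrom[[key]]) - 1L,
               stringsAsFactors = FALSE)
  }))
}

test_that("proteome comparison count matches ordered-pair enumeration", {
  expect_equal(count_proteome_comparisons(52), 2704)
  expect_equal(count_proteome_comparisons(1), 1)
  expect_error(count_proteome_comparisons(0), "positive")
  for (n in 1:20) {
    pairs <- expand.grid(a = 1:n, b = 1:n)   # ordered, incl. self
    expect_equal(count_proteome_comparisons(n), nrow(pairs))
  }
})

test_that("top-hit filter keeps k best non-self hits per query and genome", {
  hits <- data.frame(
    query = "q1", subject = paste0("t", 1:7), sgenome = "B",
    score = c(90, 70, 95, 60, 80, 85, 75), evalue = 1e-10,
    stringsAsFactors = FALSE)
  out <- filter_top_hits(hits, 5)
  expect_equal(nrow(out), 5)
  expect_equal(out$subject, c("t3", "t1", "t6", "t5", "t7"))
  # self-hit only
  self <- data.frame(query = "q1", subject = "q1", sgenome = "A",
                     score = 100, evalue = 0)
  expect_equal(nrow(filter_top_hits(self, 5)), 0)
  # fewer than k survive untouched, ordered by score
  out3 <- filter_top_hits(hits[1:3, ], 5)
  expect_equal(out3$subject, c("t3", "t1", "t2"))
  # ties: score desc, then evalue asc, then subject id
  tied <- data.frame(query = "q", subject = c("b", "a", "c"), sgenome = "B",
                     score = 50, evalue = c(1e-5, 1e-5, 1e-9))
  expect_equal(filter_top_hits(tied, 2)$subject, c("c", "a"))
  # per-target-genome budget: two genomes each keep k
  two <- data.frame(query = "q", subject = paste0("g", 1:12),
                    sgenome = rep(c("B", "C"), each = 6),
                    score = 12:1, evalue = 0)
  expect_equal(as.vector(table(filter_top_hits(two, 5)$sgenome)),
               c(5, 5))
})

test_that("tandem arrays collapse by transitive adjacency to one representative", {
  loci <- make_loci(list("A:chr1" = paste0("a", 1:5),
                         "B:chr1" = paste0("b", 1:3)))
  mutual <- function(x, y, s = 100)
    data.frame(query = c(x, y), subject = c(y, x), score = s, evalue = 0)
  hits <- rbind(mutual("a1", "a2"), mutual("a1", "b1", 80))
  out <- collapse_tandem_arrays(hits, loci)
  expect_equal(nrow(out$arrays), 2)
  expect_equal(unique(out$arrays$representative), "a1")
  expect_false(any(out$hits$query == "a2" | out$hits$subject == "a2"))
  # three consecutive mutual-hit genes form a single array
  hits3 <- rbind(mutual("a1", "a2"), mutual("a2", "a3"))
  out3 <- collapse_tandem_arrays(hits3, loci)
  expect_equal(length(unique(out3$arrays$array_id)), 1)
  expect_equal(nrow(out3$arrays), 3)
  # distant genes never group
  far <- mutual("a1", "a5")
  expect_equal(nrow(collapse_tandem_arrays(far, loci)$arrays), 0)
  expect_identical(collapse_tandem_arrays(far, loci)$hits, far)
})

test_that("diagonal and antidiagonal anchor runs chain into single blocks", {
  loci <- make_loci(list("A:chr1" = paste0("a", 1:6),
                         "B:chr1" = paste0("b", 1:6)))
  diag_hits <- data.frame(query = paste0("a", 1:5),
                          subject = paste0("b", 1:5),
                          score = 100, evalue = 0)
  b <- chain_collinear_blocks(diag_hits, loci)
  expect_length(b, 1)
  expect_equal(b[[1]]$orientation, 1)
  expect_equal(b[[1]]$n_anchors, 5)
  anti <- data.frame(query = paste0("a", 1:5),
                     subject = paste0("b", 5:1),
                     score = 100, evalue = 0)
  b2 <- chain_collinear_blocks(anti, loci)
  expect_length(b2, 1)
  expect_equal(b2[[1]]$orientation, -1)
  expect_equal(b2[[1]]$n_anchors, 5)
  expect_length(chain_collinear_blocks(diag_hits[0, ], loci), 0)
  bad <- data.frame(query = "a1", subject = "zz", score = 1, evalue = 0)
  expect_error(chain_collinear_blocks(bad, loci), "zz")
})

test_that("the chaining DP matches exhaustive monotone-chain search", {
  for (s in 1:8) {
    set.seed(s)
    n <- sample(6:11, 1)
    anc <- data.frame(q_rank = sample(0:(3 * n), n),
                      s_rank = sample(0:(3 * n), n))
    anc <- anc[!duplicated(anc$q_rank) & !duplicated(anc$s_rank), ]
    loci <- make_loci(list("A:chr1" = paste0("a", 0:(3 * max(anc$q_rank))),
                           "B:chr1" = paste0("b", 0:(3 * max(anc$s_rank)))))
    hits <- data.frame(query = paste0("a", anc$q_rank + 1),
                       subject = paste0("b", anc$s_rank + 1),
                       score = 100, evalue = 0)
    mg <- sample(c(3, 25), 1)
    blocks <- chain_collinear_blocks(hits, loci, min_anchors = 1,
                                     max_gap = mg)
    expect_equal(max(vapply(blocks, `[[`, numeric(1), "score")),
                 brute_best_chain_score(anc, max_gap = mg),
                 info = paste("seed", s))
  }
})

test_that("reported blocks satisfy monotonicity, gap and disjointness invariants", {
  cfg <- planted_transposition_config(seed = 3, out_dir = tempfile())
  tree <- scenario_species_tree()
  gs <- evolve_genomes(tree, cfg$sim, cfg$forced_events)
  loci <- gene_loci(gs)
  hits <- filter_top_hits(emit_homology_hits(gs), 5)
  blocks <- chain_collinear_blocks(hits, loci)
  expect_gt(length(blocks), 0)
  seen <- character(0)
  for (b in blocks) {
    expect_gte(b$n_anchors, 5)
    dq <- diff(b$anchors$q_rank)
    ds <- b$orientation * diff(b$anchors$s_rank)
    expect_true(all(dq > 0 & dq <= 25))
    expect_true(all(ds > 0 & ds <= 25))
    keys <- paste(b$anchors$q_gene, b$anchors$s_gene)
    expect_length(intersect(keys, seen), 0)
    seen <- c(seen, keys)
  }
  # determinism: identical inputs give identical blocks
  blocks2 <- chain_collinear_blocks(hits, loci)
  expect_identical(blocks, blocks2)
})
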
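# Fixed study scenarios used by the analysis scripts and the acceptance
# checks: an 8-species tree with a nested 3-species focal clade, and
# configurations planting a transposition (followed by a WGD) or a WGD alone
# on the clade's stem branch, against a no-event null.

#' The fixed 8-species study tree
#'
#' `((((s1,s2),(s3,(s4,s5))),(s6,s7)),s8)` with unit branch lengths except
#' the stem of the focal clade `{s3,s4,s5}`, which has length 3 (a deep stem
#' lineage, as in real plant families such as the grasses; planted events on
#' the stem then leave a well-separated internal edge in the gene trees).
#' The focal clade is deliberately nested (its parent clade is not the
#' root), so the ancestral-context genes of a transposed orthogroup do not
#' form a bipartition side of the group tree and cannot mimic a second
#' lineage-restricted monophyletic community. `s8` serves as outgroup.
#'
#' @return A rooted `phylo`.
#' @export
scenario_species_tree <- function() {
  tr <- ape::read.tree(text = "((((s1,s2),(s3,(s4,s5))),(s6,s7)),s8);")
  tr$edge.length <- rep(1, nrow(tr$edge))
  stem <- which(tr$edge[, 2] == ape::getMRCA(tr, c("s3", "s4", "s5")))
  tr$edge.length[stem] <- 3
  tr
}

#' Lineage map for the study tree
#'
#' @return Named character vector species -> lineage: the focal clade
#'   `{s3,s4,s5}` is `cladeA`; `{s1,s2}` `cladeB`; `{s6,s7}` `cladeC`;
#'   `s8` `outgroup`.
#' @export
scenario_lineage_map <- function() {
  c(s1 = "cladeB", s2 = "cladeB", s3 = "cladeA", s4 = "cladeA",
    s5 = "cladeA", s6 = "cladeC", s7 = "cladeC", s8 = "outgroup")
}

#' @rdname scenario_species_tree
#' @export
scenario_focal_clade <- function() c("s3", "s4", "s5")

.scenario_sim <- function(seed)
  sim_params(n_ancestral_genes = 200L, n_chromosomes = 4L,
             family_fraction = 0.1, rate_wgd = 0, rate_tandem = 0,
             rate_transposition = 0, rate_loss = 0, hit_score_noise = 0,
             spurious_hit_rate = 0, truncated_fraction = 0.08,
             seq_length = 500L, subst_rate = 0.02, seed = seed)

#' Study-scenario pipeline configurations
#'
#' Noise-free runs on the fixed study tree:
#' \describe{
#'   \item{null_config}{all event rates 0, nothing planted: the specificity
#'     control (no transposition must be called).}
#'   \item{planted_transposition_config}{one transposition of a family gene
#'     followed by one WGD on the stem of the focal clade; the WGD doubles
#'     the transposed community to 6 nodes so it clears the
#'     `min_community_size = 4` default.}
#'   \item{planted_wgd_config}{one WGD on the focal-clade stem: the
#'     duplication-recovery condition.}
#' }
#'
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return A `pipeline_config`.
#' @export
null_config <- function(seed = 1L, out_dir = tempfile("synnet_null_")) {
  pipeline_config(out_dir = out_dir, seed = seed, sim = .scenario_sim(seed),
                  species_tree = scenario_species_tree(),
                  lineages = scenario_lineage_map(),
                  outgroup_species = "s8")
}

#' @rdname null_config
#' @export
planted_transposition_config <- function(seed = 1L,
                                         out_dir =
                                           tempfile("synnet_transp_")) {
  cfg <- null_config(seed, out_dir)
  cfg$forced_events <- list(
    list(branch = scenario_focal_clade(), kind = "transposition",
         target = "family"),
    list(branch = scenario_focal_clade(), kind = "WGD"))
  cfg
}

#' @rdname null_config
#' @export
planted_wgd_config <- function(seed = 1L,
                               out_dir = tempfile("synnet_wgd_")) {
  cfg <- null_config(seed, out_dir)
  cfg$forced_events <- list(
    list(branch = scenario_focal_clade(), kind = "WGD"))
  cfg
}

#' Planted-WGD duplication recovery (light-weight)
#'
#' Simulates the planted-WGD scenario, builds the group gene trees and asks
#' whether any species-overlap duplication call has exactly the focal clade
#' as its shared species set. Runs only the stages needed (no synteny), so
#' replicate sweeps stay cheap.
#'
#' @param seed Integer seed.
#' @return TRUE iff a duplication call on the focal clade was produced.
#' @export
wgd_duplication_recovered <- function(seed = 1L) {
  tree <- scenario_species_tree()
  gs <- evolve_genomes(tree, .scenario_sim(seed),
                       list(list(branch = scenario_focal_clade(),
                                 kind = "WGD")))
  seqs <- emit_sequences(gs)
  gt <- build_group_trees(gs, seqs, outgroup_species = "s8")
  target <- paste(sort(scenario_focal_clade()), collapse = ",")
  for (tr in gt$trees) {
    d <- infer_duplications(tr, gt$species_map, root = "midpoint")
    if (nrow(d) && any(d$shared_species == target)) return(TRUE)
  }
  FALSE
}
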
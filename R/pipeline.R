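# Pipeline orchestration: simulate (or load) -> annotate -> collinearity ->
# network -> communities -> events, as one seeded, logged run with
# standard-format artifacts and a deterministic JSON manifest.

#' Pipeline configuration
#'
#' Collects every stage parameter with its default. All randomness flows
#' from `seed`. Either supply simulator settings (`sim`, `species_tree`,
#' `forced_events`) or external input paths (`bed_files`, `hits_file`,
#' `domain_file`, `classification_file`).
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Integer seed.
#' @param sim A [sim_params()] object (its seed is overridden by `seed`).
#' @param species_tree Optional fixed `phylo`; otherwise a random tree with
#'   `n_species` leaves is simulated.
#' @param n_species Leaves of the simulated species tree when no fixed tree
#'   is given.
#' @param forced_events Planted ground-truth events (see
#'   [evolve_genomes()]).
#' @param lineages Named vector species -> lineage label (or data.frame);
#'   defaults to one lineage per child-of-root clade of the species tree.
#' @param outgroup_species Species whose genes root the group gene trees.
#' @param bed_files,hits_file,domain_file,classification_file External-input
#'   mode: per-genome BED paths, a 12-column hit table, a 2-column domain
#'   table and a `gene_id<TAB>group` classification table.
#' @param k_hits Top non-self hits kept per query and target genome.
#' @param min_anchors,max_gap,match_score,gap_penalty Chaining parameters.
#' @param collapse_tandem Collapse tandem arrays before chaining.
#' @param cpm_k Clique-percolation k.
#' @param max_gap_fraction Alignment-trimming threshold (kept in the config
#'   for completeness; trimming applies to externally supplied alignments).
#' @param min_support Support threshold for duplication calls.
#' @param min_community_size Minimum community size for transposition calls.
#' @param min_identity Identity guard for truncated-gene classification.
#' @param refs_per_group References per group used when classifying
#'   truncated syntelogs.
#' @param log_level `"info"` or `"quiet"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("synnet_run_"),
                            seed = 1L,
                            sim = sim_params(),
                            species_tree = NULL,
                            n_species = 8L,
                            forced_events = NULL,
                            lineages = NULL,
                            outgroup_species = NULL,
                            bed_files = NULL, hits_file = NULL,
                            domain_file = NULL, classification_file = NULL,
                            k_hits = 5L, min_anchors = 5L, max_gap = 25L,
                            match_score = 50, gap_penalty = -1,
                            collapse_tandem = FALSE,
                            cpm_k = 3L, max_gap_fraction = 0.20,
                            min_support = 80, min_community_size = 4L,
                            min_identity = 0.3, refs_per_group = 3L,
                            log_level = c("info", "quiet")) {
  cfg <- as.list(environment())
  cfg$log_level <- match.arg(log_level)
  cfg$seed <- as.integer(seed)
  stopifnot(cfg$k_hits >= 1, cfg$min_anchors >= 1, cfg$max_gap >= 1,
            cfg$cpm_k >= 3, cfg$min_community_size >= 1,
            cfg$max_gap_fraction >= 0, cfg$max_gap_fraction <= 1,
            cfg$min_identity >= 0, cfg$min_identity <= 1)
  if (!is.null(cfg$sim)) {
    cfg$sim$seed <- cfg$seed
    stopifnot(inherits(cfg$sim, "sim_params"))
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Scalar keys map 1:1 onto [pipeline_config()] arguments; keys under `sim:`
#' onto [sim_params()] arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  simargs <- y$sim
  y$sim <- NULL
  cfg <- do.call(pipeline_config, y)
  if (!is.null(simargs)) {
    cfg$sim <- do.call(sim_params, simargs)
    cfg$sim$seed <- cfg$seed
  }
  cfg
}

.log <- function(cfg, ...) {
  if (identical(cfg$log_level, "info"))
    message(format(Sys.time(), "[%H:%M:%S] "), ...)
  invisible(NULL)
}

.default_lineages <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  out <- character(0)
  for (i in seq_along(kids)) {
    tips <- .tips_below(tree, kids[i])
    out[tips] <- paste0("lineage_", i)
  }
  out
}

#' Build per-group gene trees from family sequences
#'
#' Neighbor-joining trees on p-distances, one per group with at least
#' `min_leaves` member genes; truncated syntelogs are excluded from
#' phylogenies. Trees are rooted by the (lexicographically first) gene of
#' `outgroup_species` when present.
#'
#' @param gs A `genome_set`.
#' @param seqs Family sequences from [emit_sequences()].
#' @param outgroup_species Optional species label used for rooting.
#' @param min_leaves Minimum leaves per tree (default 3).
#' @return list with `trees` (named by group) and `species_map`
#'   (gene id -> species).
#' @export
build_group_trees <- function(gs, seqs, outgroup_species = NULL,
                              min_leaves = 3L) {
  g <- gs$genes[gs$genes$extant & gs$genes$family & !gs$genes$truncated, ]
  species_map <- setNames(g$species, g$gene_id)
  trees <- list()
  for (grp in sort(unique(stats::na.omit(g$group)))) {
    ids <- sort(intersect(g$gene_id[!is.na(g$group) & g$group == grp],
                          names(seqs)))
    if (length(ids) < min_leaves) next
    d <- p_distance_matrix(seqs[ids])
    tr <- nj_tree(d)
    tr$edge.length <- pmax(tr$edge.length, 0)
    if (!is.null(outgroup_species)) {
      og <- sort(ids[species_map[ids] == outgroup_species])
      if (length(og))
        tr <- ape::root(tr, outgroup = og[1], resolve.root = TRUE)
    }
    trees[[grp]] <- tr
  }
  list(trees = trees, species_map = species_map)
}

.stage_cache <- function(cfg, name, resume, compute) {
  path <- file.path(cfg$out_dir, "cache", paste0(name, ".rds"))
  if (resume && file.exists(path)) {
    .log(cfg, "stage ", name, ": reusing cached result")
    return(readRDS(path))
  }
  .log(cfg, "stage ", name, ": running")
  val <- tryCatch(compute(), error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(val, path)
  val
}

#' Run the full synteny-network pipeline
#'
#' Executes simulate/load -> annotate -> collinearity -> network ->
#' communities -> events, writes every intermediate artifact under
#' `cfg$out_dir`, and emits a manifest (parameter echo, artifact list and
#' headline counts). Identical config + seed gives a byte-identical
#' manifest.
#'
#' @param cfg A `pipeline_config`.
#' @param resume If TRUE, completed stages found in the run cache are
#'   skipped.
#' @return Invisibly, a list with all stage objects and `manifest`.
#' @export
run_pipeline <- function(cfg, resume = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  simulated <- is.null(cfg$bed_files)
  dat <- .stage_cache(cfg, "01_input", resume, function() {
    if (simulated) {
      tree <- if (!is.null(cfg$species_tree)) cfg$species_tree
              else simulate_species_tree(cfg$n_species, cfg$seed)
      gs <- evolve_genomes(tree, cfg$sim, cfg$forced_events)
      loci <- gene_loci(gs)
      hits <- emit_homology_hits(gs)
      domains <- emit_domain_table(gs)
      seqs <- emit_sequences(gs)
      write_genome_bed(gs, file.path(cfg$out_dir, "bed"))
      write_blast_table(hits, file.path(cfg$out_dir, "hits.tsv"))
      write_domain_table(domains, file.path(cfg$out_dir, "domains.tsv"))
      write_fasta(seqs, file.path(cfg$out_dir, "family.fasta"))
      write_newick(tree, file.path(cfg$out_dir, "species_tree.nwk"))
      write_event_log(gs$events, file.path(cfg$out_dir, "event_log.tsv"))
      list(gs = gs, tree = tree, loci = loci, hits = hits,
           domains = domains, seqs = seqs)
    } else {
      loci <- read_bed_loci(cfg$bed_files)
      hits <- read_blast_table(cfg$hits_file, loci)
      domains <- read_domain_table(cfg$domain_file)
      cls <- if (!is.null(cfg$classification_file))
        utils::read.table(cfg$classification_file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE) else NULL
      list(gs = NULL, tree = NULL, loci = loci, hits = hits,
           domains = domains, seqs = NULL, classification = cls)
    }
  })

  ann <- .stage_cache(cfg, "02_annotate", resume, function() {
    fam <- identify_family_members(dat$domains)
    groups <- if (simulated) {
      g <- dat$gs$genes
      setNames(g$group, g$gene_id)[fam$members]
    } else if (!is.null(dat$classification)) {
      setNames(dat$classification$group,
               dat$classification$gene_id)[fam$members]
    } else setNames(rep(NA_character_, length(fam$members)), fam$members)
    utils::write.table(
      data.frame(gene_id = fam$members, group = unname(groups)),
      file.path(cfg$out_dir, "members.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    list(members = fam$members, partial = fam$partial, groups = groups)
  })

  col <- .stage_cache(cfg, "03_collinearity", resume, function() {
    hits <- filter_top_hits(dat$hits, cfg$k_hits, dat$loci)
    arrays <- NULL
    if (cfg$collapse_tandem) {
      ct <- collapse_tandem_arrays(hits, dat$loci)
      hits <- ct$hits
      arrays <- ct$arrays
    }
    blocks <- chain_collinear_blocks(hits, dat$loci, cfg$min_anchors,
                                     cfg$max_gap, cfg$match_score,
                                     cfg$gap_penalty)
    write_collinearity(blocks, file.path(cfg$out_dir, "collinearity.txt"))
    utils::write.table(anchor_table(blocks),
                       file.path(cfg$out_dir, "anchors.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(hits = hits, blocks = blocks, arrays = arrays)
  })

  net <- .stage_cache(cfg, "04_network", resume, function() {
    trunc <- detect_truncated_syntelogs(col$blocks, ann$members,
                                        ann$partial)
    trunc_groups <- setNames(character(0), character(0))
    if (nrow(trunc) && !is.null(dat$seqs)) {
      refs <- ann$members[!is.na(ann$groups)]
      pick <- unlist(lapply(split(refs, ann$groups[refs]), function(x)
        utils::head(sort(x), cfg$refs_per_group)))
      pick <- intersect(pick, names(dat$seqs))
      q <- intersect(trunc$gene_id, names(dat$seqs))
      if (length(pick) && length(q))
        trunc_groups <- classify_by_reference(
          dat$seqs[q], dat$seqs[pick], ann$groups[pick],
          cfg$min_identity)
    }
    sp <- setNames(dat$loci$species, dat$loci$gene_id)
    all_ids <- c(ann$members, trunc$gene_id)
    gene_info <- data.frame(
      gene_id = all_ids, species = unname(sp[all_ids]),
      group = c(unname(ann$groups),
                unname(trunc_groups[trunc$gene_id])),
      status = c(rep("member", length(ann$members)),
                 rep("truncated", nrow(trunc))),
      stringsAsFactors = FALSE)
    network <- build_family_synteny_network(col$blocks, all_ids, gene_info)
    utils::write.table(trunc, file.path(cfg$out_dir, "truncated.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (igraph::vcount(network$graph) > 0) {
      export_network(network, file.path(cfg$out_dir, "network.tsv"), "tsv")
      export_network(network, file.path(cfg$out_dir, "network.graphml"),
                     "graphml")
    }
    list(network = network, truncated = trunc,
         truncated_groups = trunc_groups, gene_info = gene_info)
  })

  com <- .stage_cache(cfg, "05_communities", resume, function() {
    comms <- clique_percolation(net$network, cfg$cpm_k)
    summ <- if (length(comms)) community_summary(comms, net$network) else
      data.frame()
    if (length(comms)) {
      memb <- do.call(rbind, lapply(comms, function(c)
        data.frame(gene_id = c$nodes, community_id = c$id,
                   name = summ$name[summ$community_id == c$id])))
      utils::write.table(memb, file.path(cfg$out_dir, "communities.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(summ,
                         file.path(cfg$out_dir, "community_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      cm <- composition_matrix(comms, net$network)
      utils::write.table(cm, file.path(cfg$out_dir, "composition.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
    }
    list(communities = comms, summary = summ)
  })

  ev <- .stage_cache(cfg, "06_events", resume, function() {
    if (!simulated || is.null(dat$seqs))
      return(list(duplications = data.frame(),
                  transpositions = data.frame(),
                  ancient_tandem = data.frame(), trees = list()))
    gt <- build_group_trees(dat$gs, dat$seqs, cfg$outgroup_species)
    dups <- do.call(rbind, lapply(names(gt$trees), function(grp) {
      d <- infer_duplications(gt$trees[[grp]], gt$species_map,
                              cfg$min_support,
                              outgroup = NULL, root = "midpoint")
      if (nrow(d)) d$group <- grp
      d
    }))
    if (is.null(dups)) dups <- data.frame()
    lineages <- cfg$lineages
    if (is.null(lineages)) lineages <- .default_lineages(dat$tree)
    tps <- call_transpositions(com$communities, net$network, gt$trees,
                               lineages, cfg$min_community_size)
    grpmap <- setNames(net$gene_info$group, net$gene_info$gene_id)
    att <- flag_ancient_tandem(com$communities, grpmap, net$network)
    for (obj in list(list(dups, "duplications.tsv"),
                     list(tps, "transpositions.tsv"),
                     list(att, "ancient_tandem.tsv")))
      if (nrow(obj[[1]]))
        utils::write.table(obj[[1]], file.path(cfg$out_dir, obj[[2]]),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    list(duplications = dups, transpositions = tps, ancient_tandem = att,
         trees = gt$trees)
  })

  g <- net$network$graph
  manifest <- list(
    seed = cfg$seed,
    parameters = list(k_hits = cfg$k_hits, min_anchors = cfg$min_anchors,
                      max_gap = cfg$max_gap, cpm_k = cfg$cpm_k,
                      max_gap_fraction = cfg$max_gap_fraction,
                      min_support = cfg$min_support,
                      min_community_size = cfg$min_community_size),
    counts = list(
      n_genomes = length(unique(dat$loci$species)),
      n_genes = nrow(dat$loci),
      n_members = length(ann$members),
      n_partial = length(ann$partial),
      n_hits_filtered = nrow(col$hits),
      n_blocks = length(col$blocks),
      n_truncated_syntelogs = nrow(net$truncated),
      n_network_nodes = igraph::vcount(g),
      n_network_edges = igraph::ecount(g),
      n_anchor_pairs = net$network$n_anchor_pairs,
      syntenic_fraction_pct =
        if (length(ann$members))
          syntenic_fraction(ann$members, net$network, as_percent = TRUE)
        else NA,
      n_communities = length(com$communities),
      community_coverage_pct =
        if (igraph::vcount(g) > 0)
          community_coverage(com$communities, net$network,
                             as_percent = TRUE) else NA,
      inter_group_connections =
        if (igraph::vcount(g) > 0)
          intergroup_edge_summary(net$network)$inter_group_total else 0L,
      n_duplication_calls = nrow(ev$duplications),
      n_transposition_calls = nrow(ev$transpositions),
      n_ancient_tandem_flags = nrow(ev$ancient_tandem)),
    files = sort(grep("^cache/|^manifest\\.json$",
                      list.files(cfg$out_dir, recursive = TRUE),
                      invert = TRUE, value = TRUE)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .log(cfg, "pipeline complete: ", manifest$counts$n_network_nodes,
       " nodes, ", manifest$counts$n_communities, " communities")
  invisible(list(input = dat, annotation = ann, collinearity = col,
                 network = net, communities = com, events = ev,
                 manifest = manifest))
}

#' Validate input files without running the pipeline
#'
#' Checks BED parseability (>= 4 columns, integer coordinates), hit-table
#' column count (12), domain-table header, and newick syntax. Never throws;
#' returns a per-file report with the first offending line where
#' applicable.
#'
#' @param paths Named list: any of `bed` (character vector), `hits`,
#'   `domains`, `newick` (single paths).
#' @return data.frame: `file`, `format`, `ok`, `message`, `line`.
#' @export
validate_inputs <- function(paths) {
  rows <- list()
  add <- function(file, format, ok, message = "", line = NA_integer_)
    rows[[length(rows) + 1L]] <<- data.frame(
      file = file, format = format, ok = ok, message = message,
      line = line, stringsAsFactors = FALSE)
  for (f in paths$bed) {
    if (!file.exists(f)) { add(f, "bed", FALSE, "file not found"); next }
    lines <- readLines(f, warn = FALSE)
    bad <- NA_integer_; msg <- ""
    for (i in seq_along(lines)) {
      parts <- strsplit(lines[i], "\t")[[1]]
      if (length(parts) < 4) { bad <- i; msg <- "fewer than 4 columns"; break }
      if (is.na(suppressWarnings(as.integer(parts[2]))) ||
          is.na(suppressWarnings(as.integer(parts[3])))) {
        bad <- i; msg <- "non-integer start/end"; break
      }
    }
    add(f, "bed", is.na(bad), msg, bad)
  }
  for (f in paths$hits) {
    if (!file.exists(f)) { add(f, "hits", FALSE, "file not found"); next }
    lines <- readLines(f, warn = FALSE)
    bad <- NA_integer_; msg <- ""
    for (i in seq_along(lines)) {
      n <- length(strsplit(lines[i], "\t")[[1]])
      if (n != 12) { bad <- i; msg <- sprintf("%d columns, expected 12", n)
        break }
    }
    add(f, "hits", is.na(bad), msg, bad)
  }
  for (f in paths$domains) {
    if (!file.exists(f)) { add(f, "domains", FALSE, "file not found"); next }
    ok <- tryCatch({
      d <- read_domain_table(f)
      all(c("gene_id", "domains") %in% names(d)) && all(nzchar(d$gene_id))
    }, error = function(e) FALSE)
    add(f, "domains", isTRUE(ok),
        if (isTRUE(ok)) "" else "missing gene_id/domains columns")
  }
  for (f in paths$newick) {
    if (!file.exists(f)) { add(f, "newick", FALSE, "file not found"); next }
    err <- tryCatch({ read_newick(f); "" }, error = function(e)
      conditionMessage(e))
    add(f, "newick", !nzchar(err), err)
  }
  if (!length(rows))
    return(data.frame(file = character(0), format = character(0),
                      ok = logical(0), message = character(0),
                      line = integer(0)))
  do.call(rbind, rows)
}
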
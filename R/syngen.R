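# Genome-evolution simulator: multi-genome gene orders evolved along a known
# species tree with WGD / tandem / transposition / loss events and a ground-truth
# event log. Emits the same artifact types the real analysis consumes (gene
# orders, homology hit tables, domain tables, sequences).

#' Simulation parameters
#'
#' Bundles and validates every tunable of the genome-evolution simulator.
#' Event rates are per unit branch length; event counts per branch are Poisson
#' with mean rate x branch length.
#'
#' @param n_ancestral_genes Number of genes in the root (ancestral) genome.
#' @param n_chromosomes Number of ancestral chromosomes; genes are distributed
#'   contiguously and near-evenly.
#' @param family_fraction Fraction of ancestral genes flagged as focal-family
#'   members (these carry group labels, domains and sequences).
#' @param rate_wgd,rate_tandem,rate_transposition,rate_loss Per-branch event
#'   rates (>= 0).
#' @param hit_score_noise Standard deviation of Gaussian noise added to
#'   homology bitscores.
#' @param spurious_hit_rate Expected number of spurious (cross-orthogroup)
#'   hits as a fraction of the true hit count.
#' @param truncated_fraction Fraction of extant family genes flagged truncated
#'   (the domain table will omit one signature domain for them).
#' @param seq_length Length of simulated family-gene sequences (nt).
#' @param subst_rate Per-branch-length per-site substitution probability
#'   (must be < 0.75, the saturation limit for 4 states).
#' @param group_divergence Age (in branch-length units) separating each
#'   family orthogroup's root sequence from its subfamily-group root
#'   sequence; groups are ancient clades, so orthogroups within a group are
#'   related but clearly diverged.
#' @param seed Integer seed; all simulator randomness derives from it.
#' @param group_labels Subfamily labels cycled over family orthogroups.
#' @param base_score Bitscore of a noise-free self hit.
#' @param divergence_penalty Bitscore decrease per unit of species-tree path
#'   distance between the two genomes of a hit.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_ancestral_genes = 200L,
                       n_chromosomes = 4L,
                       family_fraction = 0.1,
                       rate_wgd = 0,
                       rate_tandem = 0.02,
                       rate_transposition = 0.02,
                       rate_loss = 0.05,
                       hit_score_noise = 0,
                       spurious_hit_rate = 0,
                       truncated_fraction = 0.08,
                       seq_length = 500L,
                       subst_rate = 0.02,
                       group_divergence = 10,
                       seed = 1L,
                       group_labels = c("I", "II", "III", "IV", "V", "VI"),
                       base_score = 500,
                       divergence_penalty = 20) {
  p <- list(n_ancestral_genes = as.integer(n_ancestral_genes),
            n_chromosomes = as.integer(n_chromosomes),
            family_fraction = family_fraction,
            rate_wgd = rate_wgd, rate_tandem = rate_tandem,
            rate_transposition = rate_transposition, rate_loss = rate_loss,
            hit_score_noise = hit_score_noise,
            spurious_hit_rate = spurious_hit_rate,
            truncated_fraction = truncated_fraction,
            seq_length = as.integer(seq_length),
            subst_rate = subst_rate,
            group_divergence = group_divergence,
            seed = as.integer(seed),
            group_labels = group_labels,
            base_score = base_score,
            divergence_penalty = divergence_penalty)
  stopifnot(p$n_ancestral_genes >= 1, p$n_chromosomes >= 1, p$seq_length >= 1)
  rates <- c(p$rate_wgd, p$rate_tandem, p$rate_transposition, p$rate_loss)
  if (any(rates < 0)) stop("event rates must be >= 0")
  props <- c(p$family_fraction, p$spurious_hit_rate, p$truncated_fraction)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (p$subst_rate < 0 || p$subst_rate >= 0.75)
    stop("subst_rate must lie in [0, 0.75)")
  if (p$hit_score_noise < 0) stop("hit_score_noise must be >= 0")
  if (p$group_divergence < 0) stop("group_divergence must be >= 0")
  class(p) <- "sim_params"
  p
}

#' Simulate a random rooted binary species tree
#'
#' @param n_species Number of leaves (>= 2); labels are `s1..sN`.
#' @param seed Integer seed; the topology is deterministic for a fixed seed.
#' @return An [ape::rtree()]-style `phylo` object, rooted and binary.
#' @export
simulate_species_tree <- function(n_species, seed = 1L) {
  if (!is.numeric(n_species) || n_species < 2)
    stop("n_species must be >= 2")
  n_species <- as.integer(n_species)
  set.seed(as.integer(seed))
  tree <- ape::rtree(n_species, tip.label = paste0("s", seq_len(n_species)))
  tree$edge.length <- abs(tree$edge.length)
  tree
}

# Resolve a forced-event branch spec (a tip label or a species set whose stem
# branch is meant) to the child-node id of that branch.
.resolve_branch <- function(tree, branch) {
  if (is.numeric(branch)) return(as.integer(branch))
  branch <- as.character(branch)
  if (length(branch) == 1L) {
    node <- match(branch, tree$tip.label)
    if (is.na(node)) stop("unknown species in forced event: ", branch)
    return(node)
  }
  miss <- setdiff(branch, tree$tip.label)
  if (length(miss)) stop("unknown species in forced event: ", miss[1])
  ape::getMRCA(tree, branch)
}

.tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, .tips_below, tree = tree))
}

#' Evolve genomes along a species tree
#'
#' Starting from an ancestral genome of `n_ancestral_genes` genes on
#' `n_chromosomes` chromosomes, genes are copied down every branch of the
#' species tree; on each branch a Poisson number of events of each kind is
#' applied in uniformly shuffled order:
#' \describe{
#'   \item{WGD}{every chromosome is duplicated wholesale onto a new chromosome,
#'     preserving gene order (so collinearity between the copies is intact).}
#'   \item{tandem}{a copy of a random gene is inserted adjacent to its parent.}
#'   \item{transposition}{one gene moves to a uniformly chosen position on
#'     another chromosome; its old and new flanking genes are recorded.}
#'   \item{loss}{a random gene is deleted.}
#' }
#' Forced events allow planting ground-truth events on a named branch, applied
#' after the sampled ones in the order given.
#'
#' @param tree A rooted binary `phylo` species tree with branch lengths.
#' @param params A [sim_params()] object.
#' @param forced_events Optional list of `list(branch=, kind=, target=)` where
#'   `branch` is a tip label, a species set (meaning the stem branch of their
#'   clade) or a node id; `kind` is one of `"WGD"`, `"tandem"`,
#'   `"transposition"`, `"loss"`; `target = "family"` restricts the affected
#'   gene to family members.
#' @return A `genome_set`: list with `genomes` (per species, a named list of
#'   chromosomes, each an ordered character vector of gene ids), `genes`
#'   (per-gene table incl. ancestors: orthogroup, family, group, truncated,
#'   parent gene, node), `events` (the ground-truth event log), plus the tree
#'   and params.
#' @export
evolve_genomes <- function(tree, params = sim_params(), forced_events = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(params, "sim_params"))
  if (is.null(tree$edge.length)) stop("species tree must have branch lengths")
  set.seed(params$seed)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L

  st <- new.env(parent = emptyenv())
  st$counter <- 0L
  st$genes <- list()     # rows appended, bound at the end
  st$events <- list()

  node_name <- function(node)
    if (node <= ntip) tree$tip.label[node] else paste0("n", node)
  new_ids <- function(n, node) {
    ids <- sprintf("%s_g%05d", node_name(node), st$counter + seq_len(n))
    st$counter <- st$counter + as.integer(n)
    ids
  }
  add_genes <- function(ids, node, orthogroup, family, group, parent,
                        t_birth = 0) {
    st$genes[[length(st$genes) + 1L]] <- data.frame(
      gene_id = ids, node = node, species = if (node <= ntip) node_name(node) else NA_character_,
      orthogroup = orthogroup, family = family, group = group,
      parent_gene = parent, t_birth = t_birth, stringsAsFactors = FALSE)
  }
  log_event <- function(node, kind, gene_ids, source_gene = NA, chrom = NA,
                        src_left = NA, src_right = NA,
                        dst_left = NA, dst_right = NA, dst_chrom = NA) {
    st$events[[length(st$events) + 1L]] <- data.frame(
      branch = node, branch_label = node_name(node), kind = kind,
      n_genes = length(gene_ids),
      gene_ids = I(list(gene_ids)), source_gene = source_gene, chrom = chrom,
      src_left = src_left, src_right = src_right,
      dst_left = dst_left, dst_right = dst_right, dst_chrom = dst_chrom,
      stringsAsFactors = FALSE)
  }

  # ancestral genome at the root
  n <- params$n_ancestral_genes
  ogs <- sprintf("og%04d", seq_len(n))
  n_fam <- round(params$family_fraction * n)
  fam_ogs <- if (n_fam > 0) sort(sample(ogs, n_fam)) else character(0)
  grp <- setNames(rep(NA_character_, n), ogs)
  if (n_fam > 0)
    grp[fam_ogs] <- rep_len(params$group_labels, n_fam)
  root_ids <- new_ids(n, root)
  add_genes(root_ids, root, ogs, ogs %in% fam_ogs, unname(grp[ogs]),
            NA_character_)
  chrom_of <- sort(rep_len(seq_len(params$n_chromosomes), n))
  root_genome <- split(root_ids, paste0("chr", chrom_of))

  # per-gene metadata lookup built incrementally for event bookkeeping
  meta <- function() do.call(rbind, st$genes)

  forced <- lapply(forced_events, function(ev) {
    ev$node <- .resolve_branch(tree, ev$branch)
    ev
  })

  # t = event time as a fraction of the branch; copies split from their
  # source gene's lineage at t (sequence evolution honours this)
  apply_wgd <- function(genome, node, gm, t) {
    old_chroms <- names(genome)
    new_ids_all <- character(0)
    k <- sum(grepl("w\\d+$", old_chroms)) + 1L
    for (ch in old_chroms) {
      src <- genome[[ch]]
      ids <- new_ids(length(src), node)
      add_genes(ids, node, gm$orthogroup[match(src, gm$gene_id)],
                gm$family[match(src, gm$gene_id)],
                gm$group[match(src, gm$gene_id)], src, t_birth = t)
      genome[[paste0(ch, "w", k)]] <- ids
      new_ids_all <- c(new_ids_all, ids)
    }
    log_event(node, "WGD", new_ids_all)
    genome
  }

  pick_gene <- function(genome, gm, target) {
    all_ids <- unlist(genome, use.names = FALSE)
    if (identical(target, "family")) {
      fam <- all_ids[gm$family[match(all_ids, gm$gene_id)]]
      if (!length(fam)) stop("no family gene available for forced event")
      sample(fam, 1L)
    } else sample(all_ids, 1L)
  }

  locate <- function(genome, gene) {
    for (ch in names(genome)) {
      i <- match(gene, genome[[ch]])
      if (!is.na(i)) return(list(chrom = ch, pos = i))
    }
    stop("gene not found in genome: ", gene)
  }

  flank <- function(vec, i)
    c(if (i > 1) vec[i - 1] else NA_character_,
      if (i < length(vec)) vec[i + 1] else NA_character_)

  apply_tandem <- function(genome, node, gm, t, target = "any") {
    g <- pick_gene(genome, gm, target)
    loc <- locate(genome, g)
    row <- gm[match(g, gm$gene_id), ]
    id <- new_ids(1L, node)
    add_genes(id, node, row$orthogroup, row$family, row$group, g,
              t_birth = t)
    v <- genome[[loc$chrom]]
    genome[[loc$chrom]] <- append(v, id, after = loc$pos)
    log_event(node, "tandem", id, source_gene = g, chrom = loc$chrom)
    genome
  }

  apply_transposition <- function(genome, node, gm, target = "any") {
    g <- pick_gene(genome, gm, target)
    loc <- locate(genome, g)
    v <- genome[[loc$chrom]]
    fl <- flank(v, loc$pos)
    genome[[loc$chrom]] <- v[-loc$pos]
    others <- setdiff(names(genome), loc$chrom)
    dst_ch <- if (length(others)) sample(others, 1L) else loc$chrom
    w <- genome[[dst_ch]]
    slot <- sample.int(length(w) + 1L, 1L) - 1L   # insert after position `slot`
    genome[[dst_ch]] <- append(w, g, after = slot)
    w2 <- genome[[dst_ch]]
    j <- match(g, w2)
    fl2 <- flank(w2, j)
    log_event(node, "transposition", g, source_gene = g, chrom = loc$chrom,
              src_left = fl[1], src_right = fl[2],
              dst_left = fl2[1], dst_right = fl2[2], dst_chrom = dst_ch)
    genome
  }

  apply_loss <- function(genome, node, gm) {
    all_ids <- unlist(genome, use.names = FALSE)
    if (length(all_ids) <= 1L) return(genome)
    g <- sample(all_ids, 1L)
    loc <- locate(genome, g)
    genome[[loc$chrom]] <- genome[[loc$chrom]][-loc$pos]
    log_event(node, "loss", g, source_gene = g, chrom = loc$chrom)
    genome
  }

  # preorder traversal
  genomes <- list()
  node_genome <- list()
  node_genome[[root]] <- root_genome
  edges <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
  preorder <- function(node) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    for (child in kids) {
      bl <- tree$edge.length[which(tree$edge[, 1] == node &
                                   tree$edge[, 2] == child)]
      parent_gm <- node_genome[[node]]
      gm <- meta()
      # speciation: fresh ids for every gene of the child lineage
      src_all <- unlist(parent_gm, use.names = FALSE)
      ids <- new_ids(length(src_all), child)
      map <- setNames(ids, src_all)
      add_genes(ids, child, gm$orthogroup[match(src_all, gm$gene_id)],
                gm$family[match(src_all, gm$gene_id)],
                gm$group[match(src_all, gm$gene_id)], src_all)
      genome <- lapply(parent_gm, function(v) unname(map[v]))
      gm <- meta()
      kinds <- c(rep("WGD", stats::rpois(1, params$rate_wgd * bl)),
                 rep("tandem", stats::rpois(1, params$rate_tandem * bl)),
                 rep("transposition",
                     stats::rpois(1, params$rate_transposition * bl)),
                 rep("loss", stats::rpois(1, params$rate_loss * bl)))
      if (length(kinds) > 1L) kinds <- sample(kinds)
      evs <- lapply(kinds, function(k) list(kind = k, target = "any"))
      for (fe in forced) if (fe$node == child)
        evs <- c(evs, list(list(kind = fe$kind,
                                target = if (is.null(fe$target)) "any"
                                         else fe$target)))
      for (k in seq_along(evs)) {
        ev <- evs[[k]]
        t <- k / (length(evs) + 1)   # evenly spaced event times on the branch
        gm <- meta()
        genome <- switch(ev$kind,
          WGD = apply_wgd(genome, child, gm, t),
          tandem = apply_tandem(genome, child, gm, t, ev$target),
          transposition = apply_transposition(genome, child, gm, ev$target),
          loss = apply_loss(genome, child, gm),
          stop("unknown event kind: ", ev$kind))
      }
      node_genome[[child]] <<- genome
      if (child <= ntip) genomes[[tree$tip.label[child]]] <<- genome
      preorder(child)
    }
  }
  preorder(root)

  genes <- meta()
  genes$truncated <- FALSE
  genes$extant <- !is.na(genes$species)
  # truncation flags on extant family genes
  ext_fam <- genes$gene_id[genes$extant & genes$family]
  if (length(ext_fam) && params$truncated_fraction > 0) {
    n_tr <- round(params$truncated_fraction * length(ext_fam))
    if (n_tr > 0)
      genes$truncated[genes$gene_id %in% sample(sort(ext_fam), n_tr)] <- TRUE
  }
  events <- if (length(st$events)) do.call(rbind, st$events) else
    data.frame(branch = integer(0), branch_label = character(0),
               kind = character(0), n_genes = integer(0),
               gene_ids = I(list()), source_gene = character(0),
               chrom = character(0), src_left = character(0),
               src_right = character(0), dst_left = character(0),
               dst_right = character(0), dst_chrom = character(0))
  out <- list(tree = tree, params = params,
              genomes = genomes[tree$tip.label[order(tree$tip.label)]],
              genes = genes, events = events)
  class(out) <- "genome_set"
  out
}

#' @export
print.genome_set <- function(x, ...) {
  cat("genome_set:", length(x$genomes), "genomes,",
      sum(x$genes$extant), "extant genes (",
      sum(x$genes$extant & x$genes$family), "family ),",
      nrow(x$events), "events\n")
  invisible(x)
}

#' Gene locus table of a simulated genome set
#'
#' @param gs A `genome_set`.
#' @return data.frame with `gene_id`, `species`, `chromosome`, `rank`
#'   (0-based order along the chromosome).
#' @export
gene_loci <- function(gs) {
  stopifnot(inherits(gs, "genome_set"))
  rows <- lapply(names(gs$genomes), function(sp) {
    gn <- gs$genomes[[sp]]
    do.call(rbind, lapply(names(gn), function(ch) {
      v <- gn[[ch]]
      if (!length(v)) return(NULL)
      data.frame(gene_id = v, species = sp, chromosome = ch,
                 rank = seq_along(v) - 1L, stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Emit noisy homology hits for a genome set
#'
#' For every ordered genome pair (including self-comparison) hits are emitted
#' between genes sharing a true orthogroup, with bitscore = base score minus a
#' divergence penalty proportional to the species-tree path distance plus
#' Gaussian noise; e-value is `exp(-score)`. Self gene-vs-itself hits are
#' included (the downstream top-hit filter removes them). Spurious
#' cross-orthogroup hits are added at `spurious_hit_rate` (as a fraction of
#' the true hit count).
#'
#' @param gs A `genome_set`.
#' @param params Defaults to the params stored in `gs`.
#' @param suppress_true If TRUE no orthogroup-based hits are emitted (boundary
#'   testing of the spurious-hit channel).
#' @return data.frame of hits: `query`, `subject`, `qgenome`, `sgenome`,
#'   `score`, `evalue` plus blast outfmt-6 filler columns.
#' @export
emit_homology_hits <- function(gs, params = gs$params, suppress_true = FALSE) {
  stopifnot(inherits(gs, "genome_set"))
  set.seed(params$seed + 1L)
  loci <- gene_loci(gs)
  g <- gs$genes[gs$genes$extant, c("gene_id", "species", "orthogroup")]
  dmat <- ape::cophenetic.phylo(gs$tree)
  species <- names(gs$genomes)
  true <- NULL
  if (!suppress_true) {
    bysp <- split(g, g$species)
    pairs <- list()
    for (a in species) for (b in species) {
      ga <- bysp[[a]]; gb <- bysp[[b]]
      m <- merge(ga, gb, by = "orthogroup")
      if (!nrow(m)) next
      d <- if (a == b) 0 else dmat[a, b]
      pairs[[paste(a, b)]] <- data.frame(
        query = m$gene_id.x, subject = m$gene_id.y,
        qgenome = a, sgenome = b,
        score = params$base_score - params$divergence_penalty * d,
        stringsAsFactors = FALSE)
    }
    true <- do.call(rbind, pairs)
  }
  n_true <- if (is.null(true)) 0L else nrow(true)
  n_spur <- round(params$spurious_hit_rate *
                  max(n_true, sum(gs$genes$extant)))
  spur <- NULL
  if (n_spur > 0) {
    ids <- g$gene_id
    qi <- sample(ids, n_spur, replace = TRUE)
    si <- sample(ids, n_spur, replace = TRUE)
    og <- setNames(g$orthogroup, g$gene_id)
    sp <- setNames(g$species, g$gene_id)
    keep <- og[qi] != og[si]
    if (any(keep))
      spur <- data.frame(query = qi[keep], subject = si[keep],
                         qgenome = unname(sp[qi[keep]]),
                         sgenome = unname(sp[si[keep]]),
                         score = params$base_score * 0.2,
                         stringsAsFactors = FALSE)
  }
  hits <- rbind(true, spur)
  if (is.null(hits) || !nrow(hits))
    return(data.frame(query = character(0), subject = character(0),
                      qgenome = character(0), sgenome = character(0),
                      score = numeric(0), evalue = numeric(0)))
  hits <- hits[!duplicated(hits[, c("query", "subject")]), , drop = FALSE]
  if (params$hit_score_noise > 0)
    hits$score <- hits$score +
      stats::rnorm(nrow(hits), 0, params$hit_score_noise)
  hits$score <- pmax(hits$score, 1)
  hits$evalue <- exp(-hits$score)
  hits <- hits[order(hits$qgenome, hits$sgenome, hits$query, hits$subject), ]
  rownames(hits) <- NULL
  hits
}

#' Split hits into per-proteome-comparison tables
#'
#' One table per unordered genome pair plus one per self-comparison, i.e.
#' n(n-1)/2 + n tables for n genomes.
#'
#' @param hits Hit table with `qgenome`/`sgenome` columns.
#' @return Named list of data.frames, names `"A__B"` with A <= B.
#' @export
split_hits_by_comparison <- function(hits) {
  key <- ifelse(hits$qgenome <= hits$sgenome,
                paste(hits$qgenome, hits$sgenome, sep = "__"),
                paste(hits$sgenome, hits$qgenome, sep = "__"))
  split(hits, key)
}

#' Emit the signature-domain table
#'
#' Family members receive both signature domains; truncated-flagged genes
#' exactly one (chosen at random under the stored seed); non-family genes are
#' absent from the table.
#'
#' @param gs A `genome_set`.
#' @param domains The two signature domain accessions.
#' @return data.frame with `gene_id` and comma-separated `domains`.
#' @export
emit_domain_table <- function(gs, domains = c("PF02362", "PF06507")) {
  stopifnot(inherits(gs, "genome_set"), length(domains) == 2L)
  set.seed(gs$params$seed + 2L)
  g <- gs$genes[gs$genes$extant & gs$genes$family, ]
  g <- g[order(g$gene_id), ]
  if (!nrow(g))
    return(data.frame(gene_id = character(0), domains = character(0)))
  dom <- ifelse(g$truncated,
                domains[sample.int(2L, nrow(g), replace = TRUE)],
                paste(domains, collapse = ","))
  data.frame(gene_id = g$gene_id, domains = dom, stringsAsFactors = FALSE)
}

#' Emit toy sequences for family genes
#'
#' One root sequence per family orthogroup (uniform over ACGT), evolved down
#' the species tree and through duplication events by per-site substitution
#' with probability `min(branch_length * subst_rate, 0.75)`; duplicate
#' lineages diverge independently from their shared parent-node gene.
#'
#' @param gs A `genome_set`.
#' @param params Defaults to the params stored in `gs`.
#' @return Named character vector of sequences for extant family genes
#'   (including truncated-flagged ones).
#' @export
emit_sequences <- function(gs, params = gs$params) {
  stopifnot(inherits(gs, "genome_set"))
  set.seed(params$seed + 3L)
  bases <- c("A", "C", "G", "T")
  L <- params$seq_length
  fam <- gs$genes[gs$genes$family, ]
  if (!nrow(fam)) return(setNames(character(0), character(0)))
  # subfamily groups are ancient clades: one root sequence per group, from
  # which each orthogroup's root diverges by `group_divergence` time units
  og_group <- tapply(fam$group, fam$orthogroup, function(x) x[1])
  roots <- sort(unique(fam$orthogroup))
  group_seq <- lapply(sort(unique(unname(og_group))), function(g)
    sample(bases, L, replace = TRUE))
  names(group_seq) <- sort(unique(unname(og_group)))

  depth <- ape::node.depth.edgelength(gs$tree)
  fam <- fam[order(depth[fam$node], fam$t_birth, fam$gene_id), ]
  edge_len <- setNames(gs$tree$edge.length, gs$tree$edge[, 2])

  mutate <- function(s, t_units) {
    p <- min(t_units * params$subst_rate, 0.7499)
    if (p <= 0) return(s)
    hit <- stats::runif(length(s)) < p
    n <- sum(hit)
    if (n) {
      cur <- s[hit]
      s[hit] <- bases[(match(cur, bases) - 1L +
                       sample.int(3L, n, replace = TRUE)) %% 4L + 1L]
    }
    s
  }

  root_seq <- lapply(roots, function(o)
    mutate(group_seq[[og_group[[o]]]], params$group_divergence))
  names(root_seq) <- roots

  # mid-branch copies split from their source gene's lineage at t_birth:
  # the source's sequence is advanced segment-by-segment, handing the state
  # at each duplication time to the newborn copy
  node_of <- setNames(fam$node, fam$gene_id)
  tb <- setNames(fam$t_birth, fam$gene_id)
  kids_on_branch <- split(fam$gene_id[fam$t_birth > 0],
                          fam$parent_gene[fam$t_birth > 0])
  seq_birth <- list()
  seq_final <- list()
  for (i in seq_len(nrow(fam))) {
    gid <- fam$gene_id[i]
    parent <- fam$parent_gene[i]
    if (is.null(seq_birth[[gid]]))
      seq_birth[[gid]] <- if (is.na(parent)) root_seq[[fam$orthogroup[i]]]
                          else seq_final[[parent]]
    bl <- edge_len[as.character(fam$node[i])]
    if (is.na(bl)) bl <- 0   # root node has no branch above
    cur <- seq_birth[[gid]]
    t_prev <- fam$t_birth[i]
    kids <- kids_on_branch[[gid]]
    if (!is.null(kids)) {
      kids <- kids[order(tb[kids])]
      for (kid in kids) {
        cur <- mutate(cur, (tb[kid] - t_prev) * bl)
        seq_birth[[kid]] <- cur
        t_prev <- tb[kid]
      }
    }
    seq_final[[gid]] <- mutate(cur, (1 - t_prev) * bl)
  }
  ext <- fam$gene_id[fam$gene_id %in% gs$genes$gene_id[gs$genes$extant]]
  out <- vapply(seq_final[ext], paste, character(1), collapse = "")
  out[order(names(out))]
}
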
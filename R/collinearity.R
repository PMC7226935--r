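# Collinearity detection: top-hit filtering, tandem-array collapsing, and an
# MCScanX-style dynamic program that chains homology anchors into collinear
# blocks per chromosome pair (ascending or descending subject ranks).

#' Count whole-proteome comparisons
#'
#' Every genome is compared against every other genome and itself, one hit
#' table per ordered genome pair: `n * (n - 1) + n = n^2` comparisons (52
#' genomes give 2704).
#'
#' @param n_genomes Number of genomes (>= 1).
#' @return Integer comparison count.
#' @export
count_proteome_comparisons <- function(n_genomes) {
  if (!is.numeric(n_genomes) || length(n_genomes) != 1 || n_genomes < 1 ||
      n_genomes != round(n_genomes))
    stop("n_genomes must be a positive integer")
  n <- as.numeric(n_genomes)
  n * (n - 1) + n
}

#' Keep the top k non-self hits per query and target genome
#'
#' Self-hits (query == subject) are removed; for each (query, target-genome)
#' pair the `k` highest-scoring hits are retained, ties broken by
#' (score desc, evalue asc, subject id lexicographic).
#'
#' @param hits Hit table (`query`, `subject`, `score`, `evalue`, ideally
#'   `sgenome`).
#' @param k Number of hits to keep per query/target-genome (default 5).
#' @param loci Optional locus table used to derive `sgenome` when absent;
#'   without genome information the filter applies per query globally.
#' @return Filtered hit table, ordered by query, target genome, score desc.
#' @export
filter_top_hits <- function(hits, k = 5L, loci = NULL) {
  if (k < 1) stop("k must be >= 1")
  if (!nrow(hits)) return(hits)
  hits <- hits[hits$query != hits$subject, , drop = FALSE]
  if (!nrow(hits)) return(hits)
  if (is.null(hits$sgenome) && !is.null(loci)) {
    sp <- setNames(loci$species, loci$gene_id)
    hits$sgenome <- unname(sp[hits$subject])
    if (is.null(hits$qgenome)) hits$qgenome <- unname(sp[hits$query])
  }
  grp <- if (is.null(hits$sgenome)) hits$query
         else paste(hits$query, hits$sgenome, sep = "\r")
  ev <- if (is.null(hits$evalue)) rep(0, nrow(hits)) else hits$evalue
  ord <- order(grp, -hits$score, ev, hits$subject)
  hits <- hits[ord, , drop = FALSE]
  grp <- grp[ord]
  keep <- stats::ave(seq_along(grp), grp, FUN = seq_along) <= k
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse tandem arrays to a representative gene
#'
#' Genes on the same chromosome within `max_tandem_gap` ranks of each other
#' that share a homology hit are grouped into arrays (by transitive closure);
#' the member with the highest intra-genome hit score represents the array in
#' chaining (ties broken lexicographically). Hits are remapped to
#' representatives and de-duplicated.
#'
#' @param hits Hit table.
#' @param loci Locus table.
#' @param max_tandem_gap Maximum rank separation within an array (default 1,
#'   i.e. adjacent genes).
#' @return list with `hits` (remapped) and `arrays` (one row per array
#'   member: `array_id`, `gene_id`, `representative`, `species`,
#'   `chromosome`, `rank`).
#' @export
collapse_tandem_arrays <- function(hits, loci, max_tandem_gap = 1L) {
  empty <- data.frame(array_id = integer(0), gene_id = character(0),
                      representative = character(0), species = character(0),
                      chromosome = character(0), rank = integer(0))
  if (!nrow(hits)) return(list(hits = hits, arrays = empty))
  sp <- setNames(loci$species, loci$gene_id)
  ch <- setNames(loci$chromosome, loci$gene_id)
  rk <- setNames(loci$rank, loci$gene_id)
  h <- hits[hits$query != hits$subject, c("query", "subject", "score")]
  adj <- h[!is.na(sp[h$query]) & !is.na(sp[h$subject]) &
           sp[h$query] == sp[h$subject] &
           ch[h$query] == ch[h$subject] &
           abs(rk[h$query] - rk[h$subject]) <= max_tandem_gap, , drop = FALSE]
  if (!nrow(adj)) return(list(hits = hits, arrays = empty))
  g <- igraph::graph_from_data_frame(adj[, 1:2], directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  # intra-genome hit score per gene (self-hits excluded above)
  intra <- h[sp[h$query] == sp[h$subject], , drop = FALSE]
  best <- tapply(intra$score, intra$query, max)
  arrays <- list()
  repmap <- character(0)
  aid <- 0L
  for (m in members) {
    if (length(m) < 2) next
    aid <- aid + 1L
    sc <- ifelse(is.na(best[m]), -Inf, best[m])
    rep_gene <- m[order(-sc, m)][1]
    repmap[m] <- rep_gene
    arrays[[aid]] <- data.frame(array_id = aid, gene_id = sort(m),
                                representative = rep_gene,
                                species = unname(sp[m[1]]),
                                chromosome = unname(ch[m[1]]),
                                rank = unname(rk[sort(m)]),
                                stringsAsFactors = FALSE)
  }
  if (!length(arrays)) return(list(hits = hits, arrays = empty))
  out <- hits
  qi <- out$query %in% names(repmap)
  si <- out$subject %in% names(repmap)
  out$query[qi] <- repmap[out$query[qi]]
  out$subject[si] <- repmap[out$subject[si]]
  out <- out[out$query != out$subject, , drop = FALSE]
  out <- out[order(out$query, out$subject, -out$score), , drop = FALSE]
  out <- out[!duplicated(out[, c("query", "subject")]), , drop = FALSE]
  rownames(out) <- NULL
  list(hits = out, arrays = do.call(rbind, arrays))
}

# DP over anchors of one chromosome pair; returns blocks (greedy, best score
# first, used anchors removed). `anc` has q_rank / s_rank columns.
.chain_one <- function(anc, min_anchors, max_gap, match_score, gap_penalty) {
  blocks <- list()
  active <- rep(TRUE, nrow(anc))
  repeat {
    idx <- which(active)
    if (length(idx) < min_anchors) break
    a <- anc[idx, , drop = FALSE]
    ord <- order(a$q_rank, a$s_rank)
    a <- a[ord, , drop = FALSE]
    n <- nrow(a)
    best <- NULL
    for (o in c(1L, -1L)) {
      s <- o * a$s_rank
      dp <- rep(match_score, n)
      par <- rep(NA_integer_, n)
      len <- rep(1L, n)
      for (j in seq_len(n)) {
        for (i in seq_len(j - 1L)) {
          dq <- a$q_rank[j] - a$q_rank[i]
          ds <- s[j] - s[i]
          if (dq <= 0 || dq > max_gap || ds <= 0 || ds > max_gap) next
          cand <- dp[i] + match_score + gap_penalty * ((dq - 1) + (ds - 1))
          if (cand > dp[j] + 1e-9) {
            dp[j] <- cand
            par[j] <- i
            len[j] <- len[i] + 1L
          }
        }
      }
      ok <- which(len >= min_anchors)
      if (!length(ok)) next
      j <- ok[order(-dp[ok], -len[ok], a$q_rank[ok], a$s_rank[ok])][1]
      cand <- list(score = dp[j], len = len[j], orient = o, end = j, par = par)
      if (is.null(best) || cand$score > best$score + 1e-9 ||
          (abs(cand$score - best$score) <= 1e-9 && cand$len > best$len))
        best <- cand
    }
    if (is.null(best)) break
    chain <- integer(0)
    j <- best$end
    while (!is.na(j)) {
      chain <- c(j, chain)
      j <- best$par[j]
    }
    blocks[[length(blocks) + 1L]] <-
      list(orientation = best$orient, score = best$score,
           anchors = a[chain, , drop = FALSE])
    active[idx[ord][chain]] <- FALSE
  }
  blocks
}

#' Chain homology anchors into collinear blocks
#'
#' Per genome pair (self-comparisons included, to recover intra-genome
#' synteny from WGDs) and chromosome pair, anchors are chained by a dynamic
#' program: extending anchor j from anchor i requires
#' `0 < delta(query rank) <= max_gap` and `0 < |delta(subject rank)| <=
#' max_gap` with a consistent sign (orientation). Chain score is
#' `sum(match_score) + gap_penalty * sum((dq - 1) + (|ds| - 1))`. Chains with
#' at least `min_anchors` anchors are reported greedily by descending score
#' with used anchors removed; the result is deterministic for fixed input.
#'
#' @param hits Filtered hit table (`query`, `subject`).
#' @param loci Locus table covering every hit gene.
#' @param min_anchors Minimum anchors per reported block (default 5, the
#'   MCScanX default).
#' @param max_gap Maximum rank gap between consecutive anchors (default 25).
#' @param match_score Score per anchor (default 50).
#' @param gap_penalty Penalty per skipped rank (default -1).
#' @return List of `collinear_block` objects: `block_id`, `genomes`,
#'   `chroms`, `orientation` (+1 ascending / -1 descending), `anchors`
#'   (data.frame `q_gene`, `s_gene`, `q_rank`, `s_rank`), `score`,
#'   `n_anchors`.
#' @export
chain_collinear_blocks <- function(hits, loci, min_anchors = 5L,
                                   max_gap = 25L, match_score = 50,
                                   gap_penalty = -1) {
  if (!nrow(hits)) return(list())
  unknown <- setdiff(unique(c(hits$query, hits$subject)), loci$gene_id)
  if (length(unknown))
    stop("hit references unknown locus: ", unknown[1])
  i <- match(hits$query, loci$gene_id)
  j <- match(hits$subject, loci$gene_id)
  a <- data.frame(q_gene = hits$query, s_gene = hits$subject,
                  q_sp = loci$species[i], q_chr = loci$chromosome[i],
                  q_rank = loci$rank[i],
                  s_sp = loci$species[j], s_chr = loci$chromosome[j],
                  s_rank = loci$rank[j], stringsAsFactors = FALSE)
  a <- a[a$q_gene != a$s_gene, , drop = FALSE]
  if (!nrow(a)) return(list())
  # canonical orientation of each anchor: species pair sorted; within a
  # self-comparison, (chrom, rank) sorted so mirrored hits coincide
  swap <- a$q_sp > a$s_sp |
    (a$q_sp == a$s_sp & (a$q_chr > a$s_chr |
                         (a$q_chr == a$s_chr & a$q_rank > a$s_rank)))
  if (any(swap)) {
    tmp <- a[swap, ]
    a[swap, c("q_gene", "q_sp", "q_chr", "q_rank")] <-
      tmp[, c("s_gene", "s_sp", "s_chr", "s_rank")]
    a[swap, c("s_gene", "s_sp", "s_chr", "s_rank")] <-
      tmp[, c("q_gene", "q_sp", "q_chr", "q_rank")]
  }
  a <- a[!duplicated(a[, c("q_gene", "s_gene")]), , drop = FALSE]
  key <- paste(a$q_sp, a$s_sp, a$q_chr, a$s_chr, sep = "\r")
  blocks <- list()
  for (k in sort(unique(key))) {
    sub <- a[key == k, , drop = FALSE]
    for (b in .chain_one(sub, min_anchors, max_gap, match_score,
                         gap_penalty)) {
      b$genomes <- c(sub$q_sp[1], sub$s_sp[1])
      b$chroms <- c(sub$q_chr[1], sub$s_chr[1])
      b$n_anchors <- nrow(b$anchors)
      b$anchors <- b$anchors[, c("q_gene", "s_gene", "q_rank", "s_rank")]
      rownames(b$anchors) <- NULL
      class(b) <- "collinear_block"
      blocks[[length(blocks) + 1L]] <- b
    }
  }
  for (i in seq_along(blocks)) blocks[[i]]$block_id <- i
  blocks
}

#' @export
print.collinear_block <- function(x, ...) {
  cat(sprintf("collinear block %d: %s(%s) ~ %s(%s), %d anchors, %s, score %.1f\n",
              x$block_id, x$genomes[1], x$chroms[1], x$genomes[2],
              x$chroms[2], x$n_anchors,
              if (x$orientation > 0) "ascending" else "descending", x$score))
  invisible(x)
}
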
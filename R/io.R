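# Readers and writers for the plain-text formats the pipeline consumes and
# emits: BED gene orders, blast outfmt-6 hit tables, 2-column domain tables,
# FASTA, newick, TSV event logs and MCScanX-style collinearity files.

#' Write per-genome gene orders as BED
#'
#' One BED file per genome, named `<species>.bed`; rank is encoded as
#' `start = rank * 1000`, `end = start + 500`.
#'
#' @param gs A `genome_set` (or a locus table from [gene_loci()]).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_genome_bed <- function(gs, dir) {
  loci <- if (inherits(gs, "genome_set")) gene_loci(gs) else gs
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(split(loci, loci$species), function(d) {
    p <- file.path(dir, paste0(d$species[1], ".bed"))
    bed <- data.frame(chrom = d$chromosome, start = d$rank * 1000L,
                      end = d$rank * 1000L + 500L, name = d$gene_id)
    utils::write.table(bed, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    p
  }, character(1))
  invisible(unname(paths))
}

#' Read gene loci from BED files
#'
#' Gene rank is taken from the order of start coordinates within each
#' chromosome (0-based).
#'
#' @param files Named character vector of BED paths; names are the species.
#'   Unnamed paths use the file basename (minus `.bed`).
#' @return Locus table: `gene_id`, `species`, `chromosome`, `rank`.
#' @export
read_bed_loci <- function(files) {
  if (is.null(names(files)) || any(!nzchar(names(files))))
    names(files) <- sub("\\.bed$", "", basename(files))
  out <- lapply(names(files), function(sp) {
    d <- utils::read.table(files[[sp]], sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
    if (ncol(d) < 4) stop("BED file needs >= 4 columns: ", files[[sp]])
    d <- d[order(d[[1]], d[[2]]), ]
    d$rank <- NA_integer_
    for (i in split(seq_len(nrow(d)), d[[1]]))
      d$rank[i] <- seq_along(i) - 1L
    data.frame(gene_id = d[[4]], species = sp, chromosome = d[[1]],
               rank = as.integer(d$rank), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a hit table in 12-column blast outfmt-6 dialect
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore. Positional columns not modelled by the simulator are
#' filled with placeholders.
#'
#' @param hits Hit table (`query`, `subject`, `score`, `evalue`).
#' @param path Output file.
#' @export
write_blast_table <- function(hits, path) {
  d <- data.frame(qseqid = hits$query, sseqid = hits$subject,
                  pident = 90, length = 100L, mismatch = 10L, gapopen = 0L,
                  qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
                  evalue = format(hits$evalue, digits = 3),
                  bitscore = round(hits$score, 1))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 12-column blast outfmt-6 hit table
#'
#' @param path File path.
#' @param loci Optional locus table used to attach `qgenome`/`sgenome`.
#' @return Hit table with `query`, `subject`, `score`, `evalue` (plus genome
#'   columns when `loci` is given).
#' @export
read_blast_table <- function(path, loci = NULL) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(d) != 12)
    stop("expected 12 blast outfmt-6 columns, got ", ncol(d), " in ", path)
  hits <- data.frame(query = d[[1]], subject = d[[2]],
                     score = d[[12]], evalue = d[[11]],
                     stringsAsFactors = FALSE)
  if (!is.null(loci)) {
    sp <- setNames(loci$species, loci$gene_id)
    hits$qgenome <- unname(sp[hits$query])
    hits$sgenome <- unname(sp[hits$subject])
  }
  hits
}

#' Write / read the 2-column domain table (TSV)
#' @param dt data.frame `gene_id`, `domains` (comma-separated).
#' @param path File path.
#' @export
write_domain_table <- function(dt, path) {
  utils::write.table(dt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_domain_table
#' @export
read_domain_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, colClasses = "character")
}

#' Write sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read FASTA into a named character vector
#' @param path File path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write the ground-truth event log as TSV
#' @param events Event log from [evolve_genomes()].
#' @param path Output file.
#' @export
write_event_log <- function(events, path) {
  d <- events
  d$gene_ids <- vapply(d$gene_ids, paste, character(1), collapse = ",")
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

#' Write blocks as an MCScanX-style collinearity file
#'
#' Block header lines `## Alignment <id>: score=<s> <spA>&<spB> <orient>`
#' followed by one anchor-pair line per anchor.
#'
#' @param blocks List of `collinear_block` objects.
#' @param path Output file.
#' @export
write_collinearity <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (b in blocks) {
    writeLines(sprintf("## Alignment %d: score=%.1f %s&%s %s", b$block_id,
                       b$score, b$genomes[1], b$genomes[2],
                       if (b$orientation > 0) "plus" else "minus"), con)
    writeLines(sprintf("%d-%d:\t%s\t%s", b$block_id,
                       seq_len(nrow(b$anchors)) - 1L,
                       b$anchors$q_gene, b$anchors$s_gene), con)
  }
  invisible(path)
}

#' Rebuild block objects from a saved anchor table
#'
#' Inverse of [anchor_table()] for downstream stages that start from the
#' TSV artifact rather than in-memory blocks.
#'
#' @param at Anchor table data.frame (or path to the TSV).
#' @param loci Optional locus table to restore anchor ranks.
#' @return List of `collinear_block` objects.
#' @export
blocks_from_anchor_table <- function(at, loci = NULL) {
  if (is.character(at))
    at <- utils::read.table(at, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  if (!nrow(at)) return(list())
  rk <- if (!is.null(loci)) setNames(loci$rank, loci$gene_id) else NULL
  lapply(split(at, at$block_id), function(d) {
    b <- list(block_id = d$block_id[1],
              genomes = c(d$q_genome[1], d$s_genome[1]),
              chroms = c(NA_character_, NA_character_),
              orientation = d$orientation[1],
              anchors = data.frame(
                q_gene = d$q_gene, s_gene = d$s_gene,
                q_rank = if (is.null(rk)) NA_integer_ else
                  unname(rk[d$q_gene]),
                s_rank = if (is.null(rk)) NA_integer_ else
                  unname(rk[d$s_gene]),
                stringsAsFactors = FALSE),
              score = NA_real_, n_anchors = nrow(d))
    class(b) <- "collinear_block"
    b
  })
}

#' Flatten blocks into a TSV anchor table
#' @param blocks List of `collinear_block` objects.
#' @return data.frame with one row per anchor.
#' @export
anchor_table <- function(blocks) {
  if (!length(blocks))
    return(data.frame(block_id = integer(0), q_gene = character(0),
                      s_gene = character(0), q_genome = character(0),
                      s_genome = character(0)))
  do.call(rbind, lapply(blocks, function(b)
    data.frame(block_id = b$block_id, q_gene = b$anchors$q_gene,
               s_gene = b$anchors$s_gene, q_genome = b$genomes[1],
               s_genome = b$genomes[2], orientation = b$orientation,
               stringsAsFactors = FALSE)))
}
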
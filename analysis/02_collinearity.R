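#!/usr/bin/env Rscript
# Stage 2 — collinear block detection.
#
# Reads the stage-1 gene orders and homology table, keeps the top five
# non-self hits per query and target genome, and chains anchors into
# collinear blocks (>= 5 anchors, rank gap <= 25) per genome and chromosome
# pair — self-comparisons included, which is how the intra-genome synteny
# created by the planted WGD is recovered.
#
# Outputs (results/analysis/02_collinearity/): MCScanX-style collinearity
# file and a flat anchor table.

library(synnet)

ind <- "results/analysis/01_data"
out <- "results/analysis/02_collinearity"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

loci <- read_bed_loci(list.files(file.path(ind, "bed"), full.names = TRUE))
hits <- read_blast_table(file.path(ind, "hits.tsv"), loci)
cat("Loaded", nrow(loci), "gene loci and", nrow(hits), "homology hits.\n")

kept <- filter_top_hits(hits, k = 5)
cat("Top-hit filter kept", nrow(kept), "of", nrow(hits),
    "hits (self-hits removed, five best per query and target genome).\n")

blocks <- chain_collinear_blocks(kept, loci)
write_collinearity(blocks, file.path(out, "collinearity.txt"))
utils::write.table(anchor_table(blocks), file.path(out, "anchors.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

n_anch <- sum(vapply(blocks, `[[`, integer(1), "n_anchors"))
intra <- sum(vapply(blocks, function(b) b$genomes[1] == b$genomes[2],
                    logical(1)))
cat("Chained", length(blocks), "collinear blocks (", n_anch, "anchors );",
    intra, "are intra-genome blocks from the planted WGD.\n")
cat("Artifacts written under", out, "\n")
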
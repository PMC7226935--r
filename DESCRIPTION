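Package: synnet
Title: Phylogenomic Synteny Network Analysis of Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and dissects microsynteny networks for a focal gene family
    across many genomes. From per-genome gene orders and pairwise homology hits
    it filters top hits, chains collinear blocks with an MCScanX-style dynamic
    program, extracts a family-anchored synteny network, detects overlapping
    communities by k-clique percolation, and reconciles communities with gene
    trees to call ancestral duplications, lineage-specific transpositions and
    ancient tandem duplications. A genome-evolution simulator with a ground-truth
    event log (whole-genome duplication, tandem duplication, single-gene
    transposition, loss) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
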
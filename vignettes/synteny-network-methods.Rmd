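---
title: "Methods: microsynteny networks, clique percolation and event inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsynteny networks, clique percolation and event inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synnet)
```

# The problem and the model

Gene families in plants expand through three qualitatively different copy
mechanisms — whole-genome duplication (WGD), tandem duplication, and
single-gene transposition — and each leaves a different *positional*
signature. After a WGD, the two copies sit in long collinear regions; a
tandem copy sits beside its parent; a transposed gene keeps its sequence
homology but loses its ancestral neighborhood. Phylogenies alone cannot
separate these mechanisms, because tree topology records descent, not
genomic context. A microsynteny network adds the context: nodes are family
genes, and an edge records that two genes occupy corresponding positions
inside a collinear block between two genomes (or two duplicated regions of
one genome). Deeply conserved subfamilies appear as dense communities;
lineage-specific transpositions appear as small communities confined to one
lineage; ancient tandem duplications followed by reciprocal losses appear
as communities mixing distinct subfamily groups.

`synnet` implements this analysis end to end and pairs it with a genome
evolution simulator so every inference rule can be validated against a
known event log.

# Stage by stage

## Family annotation

Membership uses the two-signature-domain rule: a gene is a member iff its
domain annotation contains *all* required accessions (defaults `PF02362`,
`PF06507`); genes with at least one but not all are *partial* and become
candidates for truncated-syntelog detection. Alignment trimming removes
columns whose gap fraction strictly exceeds `max_gap_fraction = 0.20` — a
column with exactly 20% gaps is kept, matching the usual "more than 20%"
convention. Classification of unlabeled genes assigns the group of the
best-scoring reference under global pairwise alignment (match +1 /
mismatch −1, gap open 4, extend 1, via Biostrings); a best alignment below
`min_identity = 0.3` returns `"unclassified"`. Ties resolve by score, then
reference id, so the mapping is deterministic.

## Top-hit filtering and collinear blocks

Every genome is compared against every other genome and itself — one hit
table per ordered pair, `n^2` comparisons in total — and only the top
`k_hits = 5` non-self hits per query *and target genome* are kept (ties:
score desc, e-value asc, subject id). Applying the budget per target genome
rather than globally keeps distant genomes represented; both readings are
one parameter apart.

Chaining is a per-chromosome-pair dynamic program: anchors are sorted by
query rank, and anchor *j* may extend anchor *i* when
`0 < Δq ≤ max_gap` and `0 < |Δs| ≤ max_gap` with a consistent sign
(ascending or descending blocks). The chain score is
`Σ match_score + gap_penalty × Σ((Δq−1) + (|Δs|−1))` with
`match_score = 50`, `gap_penalty = −1`, `max_gap = 25`, `min_anchors = 5` —
the defaults of the standard collinearity tool this stage mirrors. Blocks
are extracted greedily by descending score with used anchors removed; the
DP's optimum is verified in the test suite against exhaustive search over
all monotone anchor subsets at ≤ 12 anchors. Self-comparisons are included
deliberately: in paleopolyploid genomes most family syntelog pairs are
intra-genome. Tandem arrays (mutually hitting genes within
`max_tandem_gap = 1` ranks) can be collapsed to their highest-scoring
member before chaining.

## The network

An edge is created for every anchor pair whose two genes are family members
(or a member and a truncated syntelog); parallel anchors between the same
two genes collapse to one edge carrying the list of supporting blocks. Both
the collapsed edge count and the raw anchor-pair count are reported, since
"syntenic connections" can reasonably mean either. Partial-domain genes
anchored to members are flagged truncated, classified by reference
alignment, added to the network — and excluded from all phylogenies.

## Clique percolation

Communities are computed exactly: all k-cliques are enumerated (igraph),
two cliques are adjacent iff they share exactly k−1 nodes (implemented by
hashing (k−1)-subsets into a union–find), and communities are the connected
components of that clique graph. With the default `k = 3` every community
member keeps at least two intra-community edges; nodes in no triangle stay
unassigned, which automatically drops weakly attached syntelogs without an
extra filter. Nodes may belong to several communities. Community ids are
assigned by descending size then smallest member, making the numbering
deterministic; names follow `<sorted groups>-<node count>-<edge count>`.
k from 3 to 21 is supported; raising k makes communities smaller and more
disintegrated (covered nodes are non-increasing in k, a property the tests
assert).

## Gene trees and event rules

Group gene trees use neighbor joining (ape) on p-distances (gap-excluded
proportion of differing sites), rooted by a designated outgroup species
when available, else midpoint on request. These are a deliberate fallback:
maximum-likelihood inference is out of scope, and every rule below consumes
only monophyly and species sets, which NJ resolves at the simulator's
divergence levels.

* **Duplications** — species-overlap rule: an internal node is a
  duplication iff its two child clades share ≥ 1 species. Calls record the
  node and both child support values when the tree carries them; any value
  below `min_support = 80` flags the call low-confidence (never dropped).
  Support-free trees (e.g. NJ output) yield `low_confidence = NA` — there
  is nothing to compare.
* **Transpositions** — a community of ≥ `min_community_size = 4` nodes is
  called a transposition into lineage L iff (i) it contains ≥ 2 species,
  all mapping to L, (ii) its member-status genes are monophyletic in the
  group tree (truncated syntelogs are in the network but not the tree), and
  (iii) another community sharing a group label reaches outside L, so the
  restriction is not family-wide. This codifies as an explicit, testable
  rule what is otherwise read off figures by eye.
* **Ancient tandems** — any community whose members span ≥ 2 subfamily
  groups is flagged, with its group multiset and cross-group edges: an
  ancient tandem pair whose two members were reciprocally lost in different
  descendants leaves exactly this mixed-group syntenic signature.

# The simulator: what it emulates and what it does not

`evolve_genomes()` copies an ancestral genome (default 200 genes on 4
chromosomes, 10% family members) down a species tree; each branch receives
Poisson(rate × length) events of each kind, applied at evenly spaced times
along the branch. WGD duplicates chromosomes wholesale (new chromosome
ids), preserving collinearity as real WGDs do; tandem inserts an adjacent
copy; transposition moves one gene to a uniform position on another
chromosome (old and new flanks recorded in the event log); loss deletes a
gene. Homology hits connect genes of the same ancestral lineage with
bitscore = 500 − 20 × (species-tree path distance) + Gaussian noise, plus
optional spurious cross-lineage hits; e-values are `exp(−score)` since
downstream logic uses ranks only. Family sequences evolve by per-site
substitution (probability `branch length × subst_rate`, default 0.02, on
500-nt sequences); a mid-branch duplicate shares its source lineage's
simulated sequence up to the duplication time and diverges after.
Subfamily groups are ancient clades, so each group has a root sequence from
which its orthogroups diverge by `group_divergence = 10` time units —
within-group identity ≈ 0.6 versus ≈ 0.25 between groups, which is what
makes reference-based classification of truncated genes meaningful.
Truncation is a flag realized in the domain table (one signature domain
omitted), not literal sequence truncation, because the pipeline consumes
domain presence only.

Defaults were fixed once as a realistic desk-scale regime: 200 genes keep
chaining and clique enumeration interactive; 8% truncated mirrors the
published family's ratio of truncated to total syntelogs; event-rate
defaults (tandem 0.02, transposition 0.02, loss 0.05 per unit branch) give
sparse, attributable events. The study scenarios set all rates to zero and
plant events explicitly.

What the simulator does **not** emulate: codon structure, rate
heterogeneity, segmental (sub-chromosomal) duplications, gene conversion,
assembly fragmentation, and annotation error. Passing tests therefore
demonstrate that the inference rules are correct when their positional
assumptions hold — not that real genomes satisfy those assumptions; on
fragmented assemblies the syntenic fraction will drop for reasons the
simulator cannot reproduce.

# The study scenarios

The fixed study tree is `((((s1,s2),(s3,(s4,s5))),(s6,s7)),s8)` with unit
branch lengths except the stem of the focal clade {s3,s4,s5}, which has
length 3. Two geometric choices matter. First, the focal clade is nested —
its parent is not the root — so the ancestral-context genes of a transposed
orthogroup form a paraphyletic grade in the group tree, not a bipartition
side, and cannot mimic a second lineage-restricted monophyletic community.
Second, the deep stem gives planted events a well-separated internal edge
in the gene trees: the edge isolating a stem-planted community is a
substantial fraction of the stem, comfortably above p-distance sampling
noise at 500 sites, so recovery does not hinge on the seed.

The planted-transposition scenario moves one family gene on the stem and
then doubles the genome by a stem WGD. The order matters: the WGD copies
the transposed gene *in its new context*, producing a six-node (2 copies ×
3 species) lineage-restricted community that clears
`min_community_size = 4`; a bare three-species transposition could never be
called under that threshold. The null scenario (all rates zero) must and
does produce zero transposition calls; the planted-WGD scenario must yield
a species-overlap duplication call whose shared species are exactly the
focal clade.

# Numerical choices and degenerate inputs

* Ranks are 0-based; anchors are canonicalized (species pair sorted; within
  a self-comparison, (chromosome, rank) sorted) so mirrored hits coincide
  and no anchor is chained twice.
* DP ties break by score, then chain length, then first-anchor rank;
  community ids by size then smallest member; classification ties by
  reference id — every stage is deterministic for fixed input, and the
  pipeline manifest is byte-identical across reruns of one (config, seed).
* Degenerate inputs: empty hit tables, memberless networks and triangle-free
  graphs return empty results rather than errors; an empty alignment, a
  gene pair with no comparable sites, an unrooted tree without a rooting
  directive, and a hit referencing an unknown locus are errors that name
  the offending object.
* Problem sizes in the tests and acceptance checks — 8 genomes × 200 genes,
  brute-force oracles at ≤ 15 nodes / ≤ 12 anchors / ≤ 12 leaves, 10 WGD
  replicates — were chosen so the full suite completes in about a minute on
  one core while still exercising every rule end to end.

# Known limitations

* The greedy block extraction is simpler than the exact bookkeeping of the
  reference collinearity tool; it is oracle-checked at small scale but can
  in principle split an optimal tiling differently on dense anchor sets.
* The transposition rule's `min_community_size` is a sensitivity knob: real
  two-species lineages can never be called at the default of 4.
* NJ trees carry no support values, so duplication calls from them cannot
  be confidence-flagged; supply externally inferred trees (newick with
  internal supports) for that.
* `count_proteome_comparisons()` counts ordered pairs including self
  (n²); per-file hit tables produced by the simulator are partitioned by
  unordered pair (n(n−1)/2 + n) since the two directions of one comparison
  live in one file.
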
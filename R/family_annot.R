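# Family annotation: two-signature-domain membership, 20%-gap alignment
# trimming, and classification of unlabeled genes by best global alignment to
# classified references.

#' Identify family members by the signature-domain rule
#'
#' A gene is a `member` iff it carries ALL required domains; genes carrying at
#' least one but not all are `partial` (candidates for truncated-syntelog
#' labeling); genes with none are excluded from both sets.
#'
#' @param domain_table data.frame with `gene_id` and `domains`
#'   (comma-separated accessions, or a list column of character vectors).
#' @param required_domains Character vector of required accessions
#'   (default: the B3 and Auxin-response Pfam domains).
#' @return list with `members` and `partial` (character vectors of gene ids).
#' @export
identify_family_members <- function(domain_table,
                                    required_domains = c("PF02362",
                                                         "PF06507")) {
  if (!length(required_domains)) stop("required_domains must be nonempty")
  if (!nrow(domain_table))
    return(list(members = character(0), partial = character(0)))
  doms <- domain_table$domains
  if (!is.list(doms)) doms <- strsplit(as.character(doms), ",[ ]*")
  n_req <- vapply(doms, function(d)
    length(intersect(unique(d), required_domains)), integer(1))
  list(members = sort(domain_table$gene_id[n_req == length(required_domains)]),
       partial = sort(domain_table$gene_id[n_req > 0 &
                                           n_req < length(required_domains)]))
}

# normalise an alignment to a named character vector and validate
.as_alignment <- function(aln) {
  if (inherits(aln, "XStringSet")) aln <- setNames(as.character(aln), names(aln))
  if (is.matrix(aln)) aln <- apply(aln, 1, paste, collapse = "")
  if (!is.character(aln) || !length(aln)) stop("empty alignment")
  if (length(unique(nchar(aln))) != 1L)
    stop("alignment rows have unequal lengths")
  aln
}

#' Trim alignment columns by gap fraction
#'
#' A column is kept iff its gap fraction is `<= max_gap_fraction`; columns
#' with strictly more gaps are removed (so with 5 rows an exactly-20%-gap
#' column survives the default threshold). Row order is preserved.
#'
#' @param aln Named character vector of equal-length aligned sequences (or an
#'   `XStringSet` / character matrix).
#' @param max_gap_fraction Maximum tolerated gap fraction per column.
#' @param gap_char Gap character.
#' @return The trimmed alignment, same representation as a named character
#'   vector.
#' @export
trim_alignment_columns <- function(aln, max_gap_fraction = 0.20,
                                   gap_char = "-") {
  aln <- .as_alignment(aln)
  m <- do.call(rbind, strsplit(aln, ""))
  gaps <- colSums(m == gap_char)
  keep <- gaps / nrow(m) <= max_gap_fraction
  out <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  setNames(out, names(aln))
}

#' Classify query sequences by best-scoring classified reference
#'
#' Each query is labeled with the group of its best-scoring reference under
#' global pairwise alignment (match/mismatch scoring for the toy alphabet);
#' queries whose best alignment identity falls below `min_identity` are
#' labeled `"unclassified"`. Ties are broken by (score desc, reference id
#' lexicographic), so the result is deterministic.
#'
#' @param queries Named character vector of sequences.
#' @param references Named character vector of sequences.
#' @param ref_groups Named character vector mapping reference id to group.
#' @param min_identity Minimum fractional identity of the best alignment.
#' @return Named character vector: query id -> group label or
#'   `"unclassified"`.
#' @export
classify_by_reference <- function(queries, references, ref_groups,
                                  min_identity = 0.3) {
  if (!length(references)) stop("references must be nonempty")
  if (!all(names(references) %in% names(ref_groups)))
    stop("every reference needs a group")
  if (!length(queries)) return(setNames(character(0), character(0)))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = TRUE)
  refs <- Biostrings::DNAStringSet(references)
  ord <- order(names(refs))
  refs <- refs[ord]
  out <- vapply(names(queries), function(q) {
    al <- Biostrings::pairwiseAlignment(
      rep(Biostrings::DNAStringSet(queries[[q]]), length(refs)), refs,
      type = "global", substitutionMatrix = submat,
      gapOpening = 4, gapExtension = 1)
    sc <- Biostrings::score(al)
    best <- which.max(sc)  # first max = lexicographically smallest ref id
    ident <- Biostrings::pid(al[best], type = "PID2") / 100
    if (ident < min_identity) "unclassified"
    else unname(ref_groups[names(refs)[best]])
  }, character(1))
  out
}
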
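#' Select diseases similar to a target disease
#'
#' Returns the diseases whose recorded similarity to the target meets the
#' threshold, in decreasing order of similarity. Absent pairs count as
#' similarity 0 (unknown). The target itself is never returned.
#'
#' @param sim a `disease_similarity` table from [read_similarities()].
#' @param target target disease identifier.
#' @param min_similarity minimum similarity to qualify; default 0, so any
#'   recorded pair qualifies (the cutoff the original analysis used to
#'   arrive at its similar-disease list is not published).
#' @param max_n keep at most this many diseases; default unlimited.
#' @return character vector of disease ids, sorted by decreasing similarity,
#'   ties broken lexicographically. Empty (with a warning) if the target
#'   appears in no pair.
#' @examples
#' sim <- data.frame(disease_a = "IBD", disease_b = c("D1", "D2"),
#'                   similarity = c(0.08, 0.05))
#' class(sim) <- c("disease_similarity", "data.frame")
#' select_similar_diseases(sim, "IBD")
#' @export
select_similar_diseases <- function(sim, target, min_similarity = 0,
                                    max_n = Inf) {
  stopifnot(min_similarity >= 0)
  hit_a <- sim$disease_a == target
  hit_b <- sim$disease_b == target
  other <- c(sim$disease_b[hit_a], sim$disease_a[hit_b])
  s <- c(sim$similarity[hit_a], sim$similarity[hit_b])
  if (!length(other)) {
    warning("target disease '", target, "' absent from similarity table",
            call. = FALSE)
    return(character(0))
  }
  keep <- s >= min_similarity & other != target
  other <- other[keep]; s <- s[keep]
  o <- order(-s, other, method = "radix")
  other <- other[o]
  if (is.finite(max_n) && length(other) > max_n)
    other <- other[seq_len(max_n)]
  other
}

#' Assemble the candidate gene pool for a target disease
#'
#' Pools the known genes of every similar disease into a candidate set:
#' under guilt-by-association, genes of diseases similar to the target are
#' the candidates for association with the target itself. The target's own
#' known genes form the positive set. The entry count (total disease--gene
#' memberships among the similar diseases) typically exceeds the unique gene
#' count because similar diseases share genes.
#'
#' @param assoc a `disease_gene_assoc` object from [read_associations()].
#' @param similar ordered character vector of similar diseases, e.g. from
#'   [select_similar_diseases()].
#' @param target target disease identifier.
#' @return an object of class `candidate_set`: list with `target`,
#'   `similar_diseases` (input order preserved), `candidate_genes` (sorted
#'   union of the similar diseases' gene sets plus the target's own known
#'   genes -- positives are candidates with a known label and stay in the
#'   pool), `positive_genes` (known genes of the target), `entry_count`
#'   (memberships among similar diseases only). Similar diseases with no
#'   recorded genes are skipped with a warning.
#' @export
collect_candidates <- function(assoc, similar, target) {
  stopifnot(inherits(assoc, "disease_gene_assoc"))
  similar <- setdiff(similar, target)
  sets <- lapply(similar, function(d) genes_of(assoc, d))
  names(sets) <- similar
  absent <- similar[lengths(sets) == 0L]
  if (length(absent))
    warning(length(absent), " similar disease(s) have no recorded genes ",
            "and were skipped: ", paste(utils::head(absent, 5), collapse = ", "),
            if (length(absent) > 5) ", ..." else "", call. = FALSE)
  positive <- genes_of(assoc, target)
  structure(list(target = target,
                 similar_diseases = similar,
                 candidate_genes = sort_ids(c(unlist(sets, use.names = FALSE),
                                              positive)),
                 positive_genes = positive,
                 entry_count = sum(lengths(sets))),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf(paste0(
    "Candidate set for '%s': %d similar diseases, %d association entries,\n",
    "  %d unique candidate genes, %d known positives\n"),
    x$target, length(x$similar_diseases), x$entry_count,
    length(x$candidate_genes), length(x$positive_genes)))
  invisible(x)
}
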
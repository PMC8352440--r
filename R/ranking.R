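#' Sample negative genes from the unlabeled candidate pool
#'
#' In the positive-unlabeled setting only positive associations are known;
#' a balanced negative set is drawn uniformly without replacement from the
#' candidates that are not known positives. The draw is deterministic given
#' the seed. Sampled "negatives" may of course contain hidden true
#' positives.
#'
#' @param candidates character vector of candidate gene ids.
#' @param positives character vector of known positive gene ids.
#' @param n sample size; default `length(positives)` (balanced classes).
#' @param seed integer seed.
#' @return character vector of `n` gene ids disjoint from `positives`.
#' @export
sample_negatives <- function(candidates, positives,
                             n = length(unique(positives)), seed = 1) {
  pool <- sort_ids(setdiff(candidates, positives))
  if (n > length(pool))
    stop("requested ", n, " negatives but only ", length(pool),
         " unlabeled candidates are available", call. = FALSE)
  with_seed(seed, sort_ids(sample(pool, n)))
}

#' Score and rank unlabeled candidate genes with a final model
#'
#' Applies a fitted LS-SVM to every candidate gene outside the labeled
#' training set and ranks them by decision score. Genes scoring at or above
#' the threshold (default 0, the class boundary) are nominated as novel
#' disease-gene candidates.
#'
#' @param model an `lssvm` fit.
#' @param features a `feature_matrix` or numeric matrix with gene rownames.
#' @param labeled character vector of gene ids used for training (positives
#'   plus sampled negatives); these are excluded from the ranking.
#' @param threshold nomination threshold on the decision score; default 0.
#' @return an object of class `gene_ranking`: list with `entries` (data
#'   frame `gene`, `score`, `rank`, sorted by decreasing score, ties broken
#'   lexicographically), `threshold` and `nominated` (character vector).
#' @export
rank_candidates <- function(model, features, labeled, threshold = 0) {
  X <- feature_rows(features)
  unlabeled <- sort_ids(setdiff(rownames(X), labeled))
  if (!length(unlabeled))
    stop("no unlabeled genes to score", call. = FALSE)
  sc <- predict(model, X[unlabeled, , drop = FALSE])
  o <- order(-sc, unlabeled, method = "radix")
  entries <- data.frame(gene = unlabeled[o], score = as.vector(sc)[o],
                        rank = seq_along(o), stringsAsFactors = FALSE)
  structure(list(entries = entries, threshold = threshold,
                 nominated = entries$gene[entries$score >= threshold]),
            class = "gene_ranking")
}

#' @export
print.gene_ranking <- function(x, n = 5, ...) {
  cat(sprintf("Ranking of %d unlabeled genes; %d nominated at threshold %.3g\n",
              nrow(x$entries), length(x$nominated), x$threshold))
  print(utils::head(x$entries, n), row.names = FALSE)
  invisible(x)
}

#' Nomination stability under negative re-sampling
#'
#' The balanced negative set is an arbitrary draw; this repeats the
#' sample-train-rank cycle `r` times with different seeds and reports how
#' often each unlabeled gene is nominated, as a stability diagnostic.
#'
#' @param features a `feature_matrix` or matrix with gene rownames.
#' @param positives known positive gene ids.
#' @param r number of resampling rounds.
#' @param gamma,sigma LS-SVM hyperparameters.
#' @param threshold nomination threshold.
#' @param seed base seed; round `i` uses `seed + i - 1`.
#' @return data frame `gene`, `frequency` (fraction of rounds nominated),
#'   sorted by decreasing frequency.
#' @export
nomination_frequency <- function(features, positives, r = 10, gamma = 1,
                                 sigma = NULL, threshold = 0, seed = 1) {
  X <- feature_rows(features)
  counts <- stats::setNames(numeric(0), character(0))
  for (i in seq_len(r)) {
    negs <- sample_negatives(rownames(X), positives, seed = seed + i - 1L)
    y <- c(rep(1, length(positives)), rep(-1, length(negs)))
    fit <- lssvm(X[c(positives, negs), , drop = FALSE], y,
                 gamma = gamma, sigma = sigma)
    rk <- rank_candidates(fit, X, c(positives, negs), threshold)
    for (g in rk$nominated)
      counts[g] <- if (g %in% names(counts)) counts[g] + 1 else 1
  }
  out <- data.frame(gene = names(counts), frequency = as.numeric(counts) / r,
                    stringsAsFactors = FALSE)
  out[order(-out$frequency, out$gene, method = "radix"), , drop = FALSE]
}
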
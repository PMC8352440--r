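#' Split items into k random folds
#'
#' Assigns each item to one of `k` folds uniformly at random, with fold
#' sizes differing by at most one. The assignment is a deterministic
#' function of the item order, `k` and `seed`, and does not disturb the
#' caller's random number stream.
#'
#' @param items character vector (e.g. gene ids), no duplicates.
#' @param k number of folds, between 2 and `length(items)`.
#' @param seed integer seed.
#' @return named integer vector mapping each item to its fold in `1..k`.
#' @export
kfold_split <- function(items, k, seed) {
  n <- length(items)
  if (anyDuplicated(items)) stop("duplicate items", call. = FALSE)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop("k = ", k, " exceeds number of items (", n, ")",
                  call. = FALSE)
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  fold <- integer(n)
  perm <- with_seed(seed, sample.int(n))
  fold[perm] <- rep.int(seq_len(k), times = sizes)
  stats::setNames(fold, items)
}

# Shared input checks for the ranking metrics.
check_scores_labels <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  if (!all(labels %in% c(-1, 1)))
    stop("labels must be coded +1 / -1", call. = FALSE)
}

#' ROC curve and AUC
#'
#' The AUC is computed by the Mann--Whitney rank formula: the probability
#' that a random positive outscores a random negative, counting ties as
#' half. The ROC polyline uses one vertex per distinct score, so tied
#' scores move diagonally in a single step; the trapezoidal area of that
#' polyline equals the rank-formula AUC.
#'
#' @param scores numeric decision scores (larger = more positive).
#' @param labels labels coded +1 / -1; both classes must be present.
#' @return list with `points` (data frame `fpr`, `tpr` from (0,0) to
#'   (1,1)) and `auc`.
#' @examples
#' roc_auc(c(0.9, 0.3, 0.6, 0.2), c(1, 1, -1, -1))$auc  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  check_scores_labels(scores, labels)
  npos <- sum(labels == 1)
  nneg <- sum(labels == -1)
  if (npos == 0L || nneg == 0L)
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  o <- order(-scores)
  s <- scores[o]; l <- labels[o]
  # one curve vertex per distinct threshold; ties advance jointly
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l == 1)[last]
  fp <- cumsum(l == -1)[last]
  points <- data.frame(fpr = c(0, fp / nneg), tpr = c(0, tp / npos))
  list(points = points, auc = auc)
}

#' Precision-recall curve and area (average precision)
#'
#' Precision and recall are evaluated at every distinct score threshold
#' (descending). The area is the step-wise average precision
#' `sum_t (R_t - R_{t-1}) * P_t`, which for untied scores equals the mean of
#' the precision at each positive's rank; trapezoidal interpolation is
#' deliberately not used, as it overestimates PR area.
#'
#' @inheritParams roc_auc
#' @return list with `points` (data frame `recall`, `precision`) and
#'   `aupr` in (0, 1].
#' @examples
#' pr_auc(c(0.9, 0.3, 0.6, 0.2), c(1, 1, -1, -1))$aupr  # 10/12
#' @export
pr_auc <- function(scores, labels) {
  check_scores_labels(scores, labels)
  npos <- sum(labels == 1)
  if (npos == 0L) stop("at least one positive is required", call. = FALSE)
  o <- order(-scores)
  s <- scores[o]; l <- labels[o]
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l == 1)[last]
  npred <- seq_along(s)[last]
  recall <- tp / npos
  precision <- tp / npred
  aupr <- sum(diff(c(0, recall)) * precision)
  list(points = data.frame(recall = recall, precision = precision),
       aupr = aupr)
}

#' Cross-validated evaluation of the LS-SVM prioritizer
#'
#' Splits the labeled genes into `k` random folds; each fold is held out
#' once while an LS-SVM is trained on the rest, and the held-out decision
#' scores are pooled into a single ROC and PR curve -- matching the usual
#' presentation of one curve per method rather than per-fold averages.
#'
#' @param features a `feature_matrix` (see [build_feature_matrix()]) or a
#'   plain numeric matrix with gene rownames.
#' @param positives,negatives disjoint character vectors of gene ids, both
#'   present among the feature rows.
#' @param k number of folds; default 10.
#' @param gamma,sigma LS-SVM hyperparameters (see [lssvm()]); `sigma = NULL`
#'   applies the median heuristic within each training fold.
#' @param seed integer seed controlling the fold assignment.
#' @param stratified split positives and negatives separately so every fold
#'   holds both classes; default `FALSE` (plain random folds).
#' @return an object of class `pathsvm_cv`: list with `k`, `seed`,
#'   `fold_assignments`, `pooled` (data frame `gene`, `score`, `label`,
#'   `fold`), `roc`, `pr`, `auc`, `aupr`.
#' @export
cross_validate <- function(features, positives, negatives, k = 10,
                           gamma = 1, sigma = NULL, seed = 1,
                           stratified = FALSE) {
  X <- feature_rows(features)
  labeled <- c(positives, negatives)
  if (anyDuplicated(labeled))
    stop("positives and negatives must be disjoint", call. = FALSE)
  missing <- setdiff(labeled, rownames(X))
  if (length(missing))
    stop("labeled genes absent from feature matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  genes <- sort_ids(labeled)
  y <- stats::setNames(ifelse(genes %in% positives, 1, -1), genes)
  if (stratified) {
    fp <- kfold_split(sort_ids(positives), k, seed)
    fn <- kfold_split(sort_ids(negatives), k, seed + 1L)
    fold <- c(fp, fn)[genes]
    names(fold) <- genes
  } else {
    fold <- kfold_split(genes, k, seed)
  }
  pooled <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- genes[fold != f]
    te <- genes[fold == f]
    if (length(unique(y[tr])) < 2L)
      stop("training split for fold ", f, " contains a single class; ",
           "use stratified = TRUE", call. = FALSE)
    fit <- lssvm(X[tr, , drop = FALSE], y[tr], gamma = gamma, sigma = sigma)
    sc <- predict(fit, X[te, , drop = FALSE])
    pooled[[f]] <- data.frame(gene = te, score = as.vector(sc),
                              label = y[te], fold = f,
                              stringsAsFactors = FALSE)
  }
  pooled <- do.call(rbind, pooled)
  rownames(pooled) <- NULL
  roc <- roc_auc(pooled$score, pooled$label)
  pr <- pr_auc(pooled$score, pooled$label)
  structure(list(k = k, seed = seed, fold_assignments = fold,
                 pooled = pooled, roc = roc, pr = pr,
                 auc = roc$auc, aupr = pr$aupr),
            class = "pathsvm_cv")
}

# Accept either a feature_matrix (use its normalized block) or a matrix.
feature_rows <- function(features) {
  if (inherits(features, "feature_matrix")) return(features$normalized)
  as.matrix(features)
}

#' @export
print.pathsvm_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d): %d genes (%d+, %d-)\n",
              x$k, x$seed, nrow(x$pooled), sum(x$pooled$label == 1),
              sum(x$pooled$label == -1)))
  cat(sprintf("  pooled AUC = %.4f, AUPR = %.4f\n", x$auc, x$aupr))
  invisible(x)
}

#' Plot pooled ROC and PR curves from a cross-validation
#'
#' @param x a `pathsvm_cv` object.
#' @param which `"roc"`, `"pr"` or `"both"` (default).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.pathsvm_cv <- function(x, which = c("both", "roc", "pr"), ...) {
  which <- match.arg(which)
  if (which == "both") {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
  }
  if (which %in% c("both", "roc")) {
    graphics::plot(x$roc$points$fpr, x$roc$points$tpr, type = "l",
                   xlab = "False positive rate", ylab = "True positive rate",
                   main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
    graphics::abline(0, 1, lty = 3)
  }
  if (which %in% c("both", "pr")) {
    graphics::plot(x$pr$points$recall, x$pr$points$precision, type = "s",
                   xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "Recall", ylab = "Precision",
                   main = sprintf("PR (AUPR = %.3f)", x$aupr), ...)
  }
  invisible(x)
}
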
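test_that("k-fold split sizes, determinism and errors", {
  items10 <- sprintf("g%02d", 1:10)
  f <- kfold_split(items10, 5, seed = 1)
  expect_equal(sort(unname(table(f))), rep(2L, 5), ignore_attr = TRUE)

  items11 <- sprintf("g%02d", 1:11)
  f11 <- kfold_split(items11, 5, seed = 1)
  expect_equal(sort(as.vector(table(f11))), c(2L, 2L, 2L, 2L, 3L))

  expect_identical(kfold_split(items11, 5, seed = 3),
                   kfold_split(items11, 5, seed = 3))
  differs <- vapply(1:20, function(s)
    !identical(kfold_split(items11, 5, seed = s),
               kfold_split(items11, 5, seed = s + 100)), logical(1))
  expect_true(any(differs))

  expect_error(kfold_split(items10, 11, seed = 1), "exceeds")
  expect_error(kfold_split(items10, 1, seed = 1), "at least 2")
  expect_error(kfold_split(c("a", "a", "b"), 2, seed = 1), "duplicate")
})

test_that("k-fold split leaves the caller's RNG stream untouched", {
  set.seed(500)
  before <- .Random.seed
  invisible(kfold_split(letters, 3, seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("ROC AUC equals the rank formula on the worked examples", {
  perfect <- roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, -1, -1))
  expect_equal(perfect$auc, 1.0)
  expect_equal(perfect$points[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(as.numeric(perfect$points[nrow(perfect$points), ]), c(1, 1))

  inverted <- roc_auc(c(0.9, 0.8, 0.3, 0.1), c(-1, -1, 1, 1))
  expect_equal(inverted$auc, 0.0)

  mixed <- roc_auc(c(0.9, 0.3, 0.6, 0.2), c(1, 1, -1, -1))
  expect_equal(mixed$auc, 0.75)

  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("ROC AUC equals exhaustive pair counting and the complement identity", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(4:30, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    labels <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1] <- -labels[1]
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, auc_pair_count(scores, labels), tolerance = 1e-12)
    # inverting labels complements the area
    expect_equal(r$auc + roc_auc(scores, -labels)$auc, 1, tolerance = 1e-15)
    # trapezoidal area under the tie-aware polyline equals the rank AUC
    pts <- r$points
    trap <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                   utils::tail(pts$tpr, -1)) / 2)
    expect_equal(trap, r$auc, tolerance = 1e-12)
  }
})

test_that("PR area follows average precision on the worked examples", {
  expect_equal(pr_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, -1, -1))$aupr, 1.0)
  # mean of precision at each positive rank: (1/1 + 2/3) / 2 = 10/12
  expect_equal(pr_auc(c(0.9, 0.3, 0.6, 0.2), c(1, 1, -1, -1))$aupr, 10 / 12)
  # constant scores: a single threshold at prevalence
  expect_equal(pr_auc(rep(0.5, 10), c(rep(1, 3), rep(-1, 7)))$aupr, 0.3)
  expect_error(pr_auc(c(1, 2), c(-1, -1)), "positive")
})

test_that("cross-validation is reproducible, conserves labels, pools once", {
  bench <- generate_benchmark(benchmark_config(seed = 6))
  res <- suppressWarnings(run_pipeline(bench$network, bench$associations,
                                       bench$similarities,
                                       bench$target_disease, seed = 6))
  cv1 <- res$cv
  cv2 <- cross_validate(res$features, res$positives, res$negatives,
                        k = 10, gamma = 1, seed = 6)
  expect_identical(cv1[c("auc", "aupr", "pooled", "fold_assignments")],
                   cv2[c("auc", "aupr", "pooled", "fold_assignments")])
  # each labeled gene tested exactly once; pooled labels are a permutation
  expect_setequal(cv1$pooled$gene, c(res$positives, res$negatives))
  expect_equal(sum(cv1$pooled$label == 1), length(res$positives))
  expect_equal(sort(unique(cv1$fold_assignments)), 1:10)
  # different seed reshuffles folds
  cv3 <- cross_validate(res$features, res$positives, res$negatives,
                        k = 10, gamma = 1, seed = 60)
  expect_false(identical(cv1$fold_assignments, cv3$fold_assignments))
})

test_that("one-class training folds fail loudly, stratification avoids them", {
  X <- matrix(rnorm(24), 12, dimnames = list(sprintf("g%02d", 1:12), NULL))
  pos <- rownames(X)[1:2]
  neg <- rownames(X)[3:12]
  # with k = 6 and only 2 positives, some training split can lose a class;
  # stratified folds keep both classes in every training split
  out <- try(cross_validate(X, pos, neg, k = 2, seed = 4,
                            stratified = TRUE), silent = TRUE)
  expect_false(inherits(out, "try-error"))
  expect_error(cross_validate(X, pos, c(neg, pos[1]), k = 2, seed = 1),
               "disjoint")
})
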
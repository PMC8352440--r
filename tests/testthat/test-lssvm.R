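test_that("RBF kernel values, symmetry and limits", {
  x <- c(1, 2, 3); y <- c(2, 0, 4)
  expect_equal(rbf_kernel(x, x, 0.5), 1)
  expect_equal(rbf_kernel(x, y, 2), rbf_kernel(y, x, 2))
  # squared distance equal to 2 sigma^2 gives exp(-1)
  sq <- sum((x - y)^2)
  sigma <- sqrt(sq / 2)
  expect_equal(rbf_kernel(x, y, sigma), exp(-1))
  # huge width: everything looks close
  expect_equal(rbf_kernel(x, y, 1e8), 1, tolerance = 1e-12)
  expect_error(rbf_kernel(c(1, 2), c(1, 2, 3), 1), "dimension")
})

test_that("two-point fit matches the closed-form KKT solution", {
  x1 <- c(0, 0); x2 <- c(1, 1)
  for (gamma in c(0.5, 1, 10)) {
    for (sigma in c(0.7, 1.5)) {
      fit <- lssvm(rbind(x1, x2), c(1, -1), gamma = gamma, sigma = sigma)
      k <- rbf_kernel(x1, x2, sigma)
      a1 <- 1 / (1 - k + 1 / (2 * gamma))
      expect_equal(fit$b, 0, tolerance = 1e-10)
      expect_equal(fit$a, c(a1, -a1), tolerance = 1e-10)
      # decision at the midpoint vanishes by antisymmetry
      expect_equal(unname(predict(fit, (x1 + x2) / 2)), 0,
                   tolerance = 1e-10)
      # decision at x1 follows from the expansion
      expect_equal(unname(predict(fit, x1)),
                   (1 - k) / (1 - k + 1 / (2 * gamma)), tolerance = 1e-10)
    }
  }
})

test_that("every fit satisfies the optimality conditions", {
  set.seed(101)
  for (i in 1:10) {
    n <- sample(5:30, 1); p <- sample(2:4, 1)
    X <- matrix(rnorm(n * p), n)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- -y[1]
    gamma <- exp(runif(1, -1, 2))
    fit <- lssvm(X, y, gamma = gamma)
    K <- pathsvm:::rbf_kernel_matrix(X, X, fit$sigma)
    # linear system residual (relative) and the zero-sum constraint
    res <- max(abs(K %*% fit$a + fit$a / (2 * gamma) + fit$b - y))
    expect_lte(res, 1e-8 * max(abs(y)))
    expect_lte(abs(sum(fit$a)), 1e-8)
    # each coefficient is 2*gamma times its training residual
    expect_lt(max(abs(fit$a - 2 * gamma * residuals(fit))), 1e-6)
  }
})

test_that("large gamma interpolates the training labels", {
  set.seed(7)
  X <- matrix(rnorm(16), 8)
  y <- c(1, 1, 1, 1, -1, -1, -1, -1)
  fit <- lssvm(X, y, gamma = 1e8, sigma = 1)
  expect_lt(max(abs(fitted(fit) - y)), 1e-3)
})

test_that("training row permutation leaves the decision function unchanged", {
  set.seed(9)
  X <- matrix(rnorm(40), 20)
  y <- rep(c(1, -1), 10)
  fit1 <- lssvm(X, y, gamma = 2, sigma = 1.3)
  perm <- sample(20)
  fit2 <- lssvm(X[perm, ], y[perm], gamma = 2, sigma = 1.3)
  probe <- matrix(rnorm(20), 10)
  expect_equal(predict(fit1, probe), predict(fit2, probe),
               tolerance = 1e-9)
})

test_that("decision values match independent references on 20 random datasets", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(10:50, 1); p <- sample(2:5, 1)
    X <- matrix(rnorm(n * p), n)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- -y[1]
    gamma <- exp(runif(1, -1, 3)); sigma <- exp(runif(1, -0.5, 1))
    fit <- lssvm(X, y, gamma = gamma, sigma = sigma)
    probe <- matrix(rnorm(10 * p), 10)
    f <- unname(predict(fit, probe))
    # exact reference by an independent numerical route
    eig <- lssvm_eigen_reference(X, y, gamma, sigma)
    K2 <- pathsvm:::rbf_kernel_matrix(probe, X, sigma)
    expect_equal(f, as.vector(K2 %*% eig$a + eig$b), tolerance = 1e-6)
    # direct minimizer of the structural-risk objective
    pri <- lssvm_primal_reference(X, y, gamma, sigma)
    expect_equal(f, as.vector(K2 %*% pri$c + pri$b), tolerance = 1e-3)
  }
})

test_that("degenerate and invalid inputs are rejected clearly", {
  X <- matrix(rnorm(10), 5)
  expect_error(lssvm(X, rep(1, 5)), "both classes")
  expect_error(lssvm(X, c(1, -1, 1, -1, 0)), "\\+1 / -1")
  expect_error(lssvm(X[1, , drop = FALSE], 1), "at least 2")
  # coincident points break the median heuristic with a clear message
  expect_error(lssvm(matrix(1, 4, 2), c(1, 1, -1, -1)), "median")
  fit <- lssvm(X, c(1, -1, 1, -1, 1))
  expect_error(predict(fit, matrix(1, 1, 5)), "dimension")
})

test_that("class prediction thresholds scores with ties going positive", {
  set.seed(2)
  X <- rbind(matrix(rnorm(10, -2), 5), matrix(rnorm(10, 2), 5))
  y <- rep(c(-1, 1), each = 5)
  fit <- lssvm(X, y, gamma = 5)
  sc <- predict(fit, X)
  cls <- predict(fit, X, type = "class")
  expect_equal(unname(cls), ifelse(sc >= 0, 1, -1))
  # explicit threshold: scores equal to it map to +1
  thr <- unname(sc[3])
  expect_equal(unname(predict(fit, X[3, , drop = FALSE], type = "class",
                              threshold = thr)), 1)
})

test_that("model accessors are coherent", {
  set.seed(5)
  X <- matrix(rnorm(24), 12)
  y <- rep(c(1, -1), 6)
  fit <- lssvm(X, y)
  expect_equal(unname(coef(fit)[1]), fit$b)
  expect_equal(unname(coef(fit)[-1]), fit$a)
  expect_equal(residuals(fit), y - unname(predict(fit, X)))
  s <- summary(fit)
  expect_lt(s$kkt_residual, 1e-8)
  expect_output(print(fit), "Least-squares SVM")
})
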
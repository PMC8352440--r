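#' Gaussian radial basis kernel
#'
#' `K(x, y) = exp(-||x - y||^2 / (2 sigma^2))`, where `||.||` is the
#' Euclidean norm. Symmetric, equal to 1 at zero distance, strictly
#' decreasing in distance.
#'
#' @param x,y numeric vectors of equal length.
#' @param sigma kernel width, positive.
#' @return kernel value in (0, 1].
#' @export
rbf_kernel <- function(x, y, sigma) {
  if (length(x) != length(y))
    stop("dimension mismatch: length(x) = ", length(x),
         ", length(y) = ", length(y), call. = FALSE)
  stopifnot(sigma > 0)
  exp(-sum((x - y)^2) / (2 * sigma^2))
}

# Kernel matrix between the rows of X and Y (both matrices).
rbf_kernel_matrix <- function(X, Y, sigma) {
  if (ncol(X) != ncol(Y))
    stop("dimension mismatch: ", ncol(X), " vs ", ncol(Y), " features",
         call. = FALSE)
  sq <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  sq[sq < 0] <- 0  # guard tiny negative round-off
  exp(-sq / (2 * sigma^2))
}

# Median pairwise Euclidean distance of training rows (median heuristic).
median_heuristic <- function(X) {
  dd <- as.vector(stats::dist(X))
  dd <- dd[dd > 0]
  if (!length(dd))
    stop("cannot apply the median distance heuristic: all training points ",
         "coincide; supply sigma explicitly", call. = FALSE)
  stats::median(dd)
}

#' Fit a least-squares support vector machine
#'
#' Trains the classifier at the core of the prioritization method: a kernel
#' regression on labels coded +1/-1 whose structural risk
#' `gamma * sum(eps_i^2) + ||w||^2 / 2` is minimized via Lagrange
#' multipliers. The stationarity conditions eliminate the primal weights and
#' reduce training to one symmetric linear system in the dual coefficients
#' `a` and bias `b`:
#' \deqn{\sum_i a_i = 0, \qquad
#'       \Omega a + \frac{a}{2\gamma} + b\,\mathbf{1} = y,}
#' with \eqn{\Omega_{ij} = K(x_i, x_j)} the RBF kernel matrix. The
#' conditions also give the identity `a_i = 2 * gamma * eps_i` relating each
#' coefficient to its training residual; `summary()` reports the residuals
#' of both the linear system and this identity.
#'
#' @param x numeric matrix of training feature vectors (rows = points;
#'   rownames, if present, are carried as gene ids).
#' @param y labels, one per row of `x`, coded +1 / -1; both classes must be
#'   present.
#' @param gamma regularization weight on the squared training error,
#'   positive; larger values fit the training labels more tightly. Default
#'   1.
#' @param sigma RBF kernel width; default `NULL` applies the median
#'   heuristic (median pairwise Euclidean distance of the training rows).
#' @return an object of class `lssvm`: list with `x`, `y`, dual
#'   coefficients `a`, bias `b`, `sigma`, `gamma`, `kkt_residual` (relative
#'   max-norm residual of the linear system) and the matched call.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(20, -1), 10), matrix(rnorm(20, 1), 10))
#' fit <- lssvm(x, rep(c(-1, 1), each = 10), gamma = 1)
#' fit
#' predict(fit, x[1:2, ])
#' @seealso [predict.lssvm()], [cross_validate()], [rank_candidates()]
#' @export
lssvm <- function(x, y, gamma = 1, sigma = NULL) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 training points", call. = FALSE)
  if (length(y) != n) stop("length(y) must equal nrow(x)", call. = FALSE)
  if (!all(y %in% c(-1, 1)))
    stop("labels must be coded +1 / -1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("both classes must be present in the training labels", call. = FALSE)
  stopifnot(gamma > 0)
  if (is.null(sigma)) sigma <- median_heuristic(x)
  stopifnot(sigma > 0)
  K <- rbf_kernel_matrix(x, x, sigma)
  A <- rbind(c(0, rep(1, n)),
             cbind(1, K + diag(n) / (2 * gamma)))
  sol <- tryCatch(solve(A, c(0, y)), error = function(e)
    stop("the KKT linear system is singular (", conditionMessage(e),
         "); distinct training points, a smaller gamma (larger 1/(2*gamma) ",
         "diagonal) or a different sigma may help", call. = FALSE))
  b <- unname(sol[1L])
  a <- unname(sol[-1L])
  resid <- max(abs(K %*% a + a / (2 * gamma) + b - y))
  rel <- resid / max(abs(y))
  structure(list(x = x, y = y, a = as.vector(a), b = b, sigma = sigma,
                 gamma = gamma, kkt_residual = rel,
                 call = match.call()),
            class = "lssvm")
}

#' Decision scores and class predictions from a fitted LS-SVM
#'
#' The decision function is the kernel expansion
#' `f(x) = sum_j a_j K(x_j, x) + b`; larger scores mean more likely positive
#' class. The raw score is a ranking score, not a calibrated probability.
#'
#' @param object an `lssvm` fit.
#' @param newdata numeric matrix (or single vector) of points to score.
#' @param type `"score"` for decision values (default) or `"class"` for
#'   +1/-1 labels.
#' @param threshold class boundary for `type = "class"`; scores equal to
#'   the threshold go to +1. Default 0.
#' @param ... unused.
#' @return numeric vector of scores, or of +1/-1 labels; named by `newdata`
#'   rownames when present.
#' @export
predict.lssvm <- function(object, newdata, type = c("score", "class"),
                          threshold = 0, ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  K <- rbf_kernel_matrix(newdata, object$x, object$sigma)
  f <- as.vector(K %*% object$a + object$b)
  names(f) <- rownames(newdata)
  if (type == "class") {
    cls <- ifelse(f >= threshold, 1, -1)
    return(cls)
  }
  f
}

#' @export
fitted.lssvm <- function(object, ...) predict(object, object$x)

#' @export
residuals.lssvm <- function(object, ...) object$y - fitted(object)

#' @export
coef.lssvm <- function(object, ...) {
  a <- object$a
  names(a) <- rownames(object$x)
  c(b = object$b, a)
}

#' @export
print.lssvm <- function(x, ...) {
  cat("Least-squares SVM (RBF kernel)\n")
  cat(sprintf("  n = %d training points, %d features\n",
              nrow(x$x), ncol(x$x)))
  cat(sprintf("  sigma = %.6g, gamma = %.6g, bias b = %.6g\n",
              x$sigma, x$gamma, x$b))
  invisible(x)
}

#' @export
summary.lssvm <- function(object, ...) {
  eps <- residuals(object)
  out <- list(n = nrow(object$x), p = ncol(object$x),
              sigma = object$sigma, gamma = object$gamma, b = object$b,
              kkt_residual = object$kkt_residual,
              sum_a = sum(object$a),
              # stationarity identity a_i = 2*gamma*eps_i
              risk_identity_gap = max(abs(object$a - 2 * object$gamma * eps)),
              training_accuracy = mean(sign(fitted(object)) == object$y |
                                         fitted(object) == 0 & object$y == 1))
  class(out) <- "summary.lssvm"
  out
}

#' @export
print.summary.lssvm <- function(x, ...) {
  cat("Least-squares SVM (RBF kernel)\n")
  cat(sprintf("  n = %d points, %d features; sigma = %.6g, gamma = %.6g\n",
              x$n, x$p, x$sigma, x$gamma))
  cat(sprintf("  bias b = %.6g; sum(a) = %.3g; KKT residual = %.3g\n",
              x$b, x$sum_a, x$kkt_residual))
  cat(sprintf("  |a - 2*gamma*eps| max = %.3g; training accuracy = %.3f\n",
              x$risk_identity_gap, x$training_accuracy))
  invisible(x)
}

#' @export
plot.lssvm <- function(x, ...) {
  f <- fitted(x)
  cls <- factor(x$y, levels = c(-1, 1), labels = c("negative", "positive"))
  graphics::boxplot(f ~ cls, xlab = "training label",
                    ylab = "decision score",
                    main = "LS-SVM training decision scores", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
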
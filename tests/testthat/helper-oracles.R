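# Independent oracles used across the suite. These deliberately take
# different computational routes from the package code they check.

# All-simple-paths shortest distances by exhaustive recursion (tiny graphs).
brute_force_distance <- function(network, source, target,
                                 transform = "identity") {
  len <- edge_length(network$edges$weight, transform)
  edges <- network$edges
  best <- Inf
  walk <- function(node, visited, acc) {
    if (acc >= best) return()
    if (node == target) { best <<- acc; return() }
    hit <- which(edges$from == node | edges$to == node)
    for (e in hit) {
      nxt <- if (edges$from[e] == node) edges$to[e] else edges$from[e]
      if (nxt %in% visited) next
      walk(nxt, c(visited, nxt), acc + len[e])
    }
  }
  walk(source, source, 0)
  best
}

# Random connected weighted graph on <= max_nodes nodes: a random spanning
# tree plus random extra edges (connectivity by construction).
random_connected_network <- function(seed, max_nodes = 8) {
  set.seed(seed)
  n <- sample(3:max_nodes, 1)
  nodes <- sprintf("n%02d", sample(99, n))
  from <- character(0); to <- character(0)
  for (i in 2:n) {
    j <- sample(i - 1, 1)
    from <- c(from, nodes[j]); to <- c(to, nodes[i])
  }
  extra <- sample(0:3, 1)
  for (k in seq_len(extra)) {
    ij <- sample(n, 2)
    key <- paste(sort(nodes[ij]), collapse = "\t")
    have <- paste(pmin(from, to), pmax(from, to), sep = "\t")
    if (key %in% have) next
    from <- c(from, nodes[ij[1]]); to <- c(to, nodes[ij[2]])
  }
  w <- round(runif(length(from), 0.1, 2), 3)
  pathsvm:::new_network(from, to, w)
}

# LS-SVM reference 1: exact solve of the same optimality conditions by a
# different numerical route (eigendecomposition + Schur complement).
lssvm_eigen_reference <- function(X, y, gamma, sigma) {
  n <- nrow(X)
  K <- exp(-as.matrix(stats::dist(X))^2 / (2 * sigma^2))
  e <- eigen(K + diag(n) / (2 * gamma), symmetric = TRUE)
  Minv <- e$vectors %*% (t(e$vectors) / e$values)
  b <- sum(Minv %*% y) / sum(Minv)
  a <- as.vector(Minv %*% (y - b))
  list(a = a, b = b, K = K)
}

# LS-SVM reference 2: direct numerical minimization of the structural-risk
# objective gamma * sum(eps^2) + ||w||^2 / 2 over the kernel span, tying the
# linear-system solution back to the Lagrangian it came from.
lssvm_primal_reference <- function(X, y, gamma, sigma) {
  n <- nrow(X)
  K <- exp(-as.matrix(stats::dist(X))^2 / (2 * sigma^2))
  obj <- function(par) {
    cv <- par[1:n]; b <- par[n + 1]
    r <- y - as.vector(K %*% cv) - b
    gamma * sum(r^2) + 0.5 * sum(cv * as.vector(K %*% cv))
  }
  grad <- function(par) {
    cv <- par[1:n]; b <- par[n + 1]
    r <- y - as.vector(K %*% cv) - b
    c(-2 * gamma * as.vector(K %*% r) + as.vector(K %*% cv),
      -2 * gamma * sum(r))
  }
  par <- rep(0, n + 1)
  for (round in 1:50) {
    fit <- stats::optim(par, obj, grad, method = "BFGS",
                        control = list(maxit = 5000, reltol = 1e-16))
    par <- fit$par
    if (sqrt(sum(grad(par)^2)) < 1e-10) break
  }
  list(c = par[1:n], b = par[n + 1])
}

# AUC by exhaustive concordant-pair counting (ties count half).
auc_pair_count <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == -1]
  total <- 0
  for (sp in pos) for (sn in neg)
    total <- total + (sp > sn) + 0.5 * (sp == sn)
  total / (length(pos) * length(neg))
}

# Tiny association table builder.
make_assoc <- function(...) {
  pairs <- list(...)
  pathsvm:::new_associations(data.frame(
    disease_id = vapply(pairs, `[`, "", 1),
    gene_id = vapply(pairs, `[`, "", 2),
    stringsAsFactors = FALSE))
}

make_sim <- function(a, b, s) {
  out <- data.frame(disease_a = a, disease_b = b, similarity = s,
                    stringsAsFactors = FALSE)
  class(out) <- c("disease_similarity", "data.frame")
  out
}
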
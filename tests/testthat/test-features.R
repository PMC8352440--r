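test_that("edge length transforms and their validity domains", {
  expect_equal(edge_length(0.5, "identity"), 0.5)
  expect_equal(edge_length(0.5, "reciprocal"), 2.0)
  expect_equal(edge_length(0.5, "neg_log"), -log(0.5))
  expect_equal(edge_length(0.5, "one_minus"), 0.5)
  expect_error(edge_length(1.0, "one_minus"), "weight < 1")
  expect_error(edge_length(1.0, "neg_log"), "weight < 1")
  expect_error(edge_length(-1, "identity"), "positive")
  expect_error(edge_length(0, "reciprocal"), "positive")
})

test_that("dijkstra follows the cheapest path, not the direct edge", {
  net <- example_network()  # A-B 1, B-C 2, A-C 4, C-D 1
  sp <- dijkstra(net, "A")
  expect_equal(unname(sp$d["A"]), 0)
  expect_equal(unname(sp$d["C"]), 3)   # A-B-C beats A-C (4)
  expect_equal(unname(sp$d["D"]), 4)   # A-B-C-D
  expect_equal(unname(sp$p["D"]), "C")
  # predecessor chain reconstructs the distance
  node <- "D"; acc <- 0
  while (!is.na(sp$p[node])) {
    prev <- unname(sp$p[node])
    e <- net$edges[(net$edges$from == prev & net$edges$to == node) |
                   (net$edges$from == node & net$edges$to == prev), ]
    acc <- acc + e$weight
    node <- prev
  }
  expect_equal(acc, unname(sp$d["D"]))
  expect_error(dijkstra(net, "Z"), "not in network")
})

test_that("dijkstra equals exhaustive simple-path enumeration on 30 graphs", {
  for (seed in 0:29) {
    net <- random_connected_network(seed)
    for (src in net$nodes) {
      sp <- dijkstra(net, src)
      for (tgt in net$nodes) {
        expect_equal(unname(sp$d[tgt]), brute_force_distance(net, src, tgt),
                     tolerance = 1e-12,
                     label = sprintf("seed %d, %s->%s", seed, src, tgt))
      }
    }
  }
})

test_that("distances are symmetric, metric, and monotone under edge addition", {
  for (seed in c(3, 11, 19)) {
    net <- random_connected_network(seed)
    n <- length(net$nodes)
    D <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
    for (src in net$nodes) D[src, ] <- dijkstra(net, src)$d[net$nodes]
    expect_equal(D, t(D), tolerance = 1e-12)
    for (i in 1:n) for (j in 1:n) for (k in 1:n)
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
    # independent cross-check against an established graph library
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE)
    Dig <- igraph::distances(g, weights = igraph::E(g)$weight)
    expect_equal(D, Dig[net$nodes, net$nodes], tolerance = 1e-12)
    # adding a shortcut never increases any distance
    missing <- which(upper.tri(D) & D > 0, arr.ind = TRUE)
    pick <- missing[1, ]
    aug <- pathsvm:::new_network(
      c(net$edges$from, net$nodes[pick[1]]),
      c(net$edges$to, net$nodes[pick[2]]),
      c(net$edges$weight, 0.05))
    D2 <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
    for (src in net$nodes) D2[src, ] <- dijkstra(aug, src)$d[net$nodes]
    expect_true(all(D2 <= D + 1e-12))
  }
})

test_that("gene-disease feature: membership, adjacency and unreachable cases", {
  net <- pathsvm:::new_network(c("g1", "g3"), c("g2", "g4"), c(0.7, 0.5))
  sp <- dijkstra(net, "g1")
  # member of the disease set: membership value (0 by default, 1 on request)
  expect_equal(gene_disease_feature(sp, "g1", c("g1", "g2")), 0)
  expect_equal(gene_disease_feature(sp, "g1", c("g1", "g2"),
                                    membership_value = 1), 1)
  # single edge of length 0.7 to the only disease gene
  expect_equal(gene_disease_feature(sp, "g1", "g2"), 0.7)
  # disconnected component: unreachable sentinel
  expect_true(is.na(gene_disease_feature(sp, "g1", "g3")))
  expect_equal(gene_disease_feature(sp, "g1", "g3", unreachable = 99), 99)
})

test_that("feature matrix z-scoring and unreachable imputation", {
  # two components: g1-g2-g3 connected, g4-g5 separate
  net <- pathsvm:::new_network(c("g1", "g2", "g4"), c("g2", "g3", "g5"),
                               c(1, 2, 1))
  assoc <- make_assoc(c("DA", "g3"), c("DB", "g5"), c("T", "g1"))
  cand <- collect_candidates(assoc, c("DA", "DB"), "T")
  fm <- build_feature_matrix(net, cand, assoc, transform = "identity")
  expect_equal(fm$dimensions, c("DA", "DB"))
  expect_equal(fm$genes, c("g1", "g3", "g5"))
  # raw distances: g1 to DA's g3 = 3; g1 unreachable to DB -> 1.5 * max
  expect_equal(fm$raw["g1", "DA"], 3)
  expect_equal(fm$raw["g3", "DA"], 0)       # member
  expect_equal(fm$raw["g5", "DB"], 0)       # member
  expect_equal(fm$raw["g5", "DA"], 1.5 * 3) # imputed beyond max finite 3
  # z-scored DA column: mean 0, sample sd 1
  expect_lt(abs(mean(fm$normalized[, "DA"])), 1e-9)
  expect_lt(abs(sd(fm$normalized[, "DA"]) - 1), 1e-9)
  # DB column: members at 0, unreachables imputed to the max finite (0),
  # zero variance, normalized to zeros
  expect_true(all(fm$normalized[, "DB"] == 0))
})

test_that("z-scoring matches the hand computation and zero-variance rule", {
  # raw column [1,2,3] -> normalized [-1,0,1] under sample sd
  raw <- c(1, 2, 3)
  expect_equal((raw - mean(raw)) / sd(raw), c(-1, 0, 1))
  # constant raw column maps to all zeros in a built matrix
  net <- pathsvm:::new_network(c("a", "b"), c("b", "c"), c(1, 1))
  assoc <- make_assoc(c("DA", "a"), c("DA", "b"), c("DA", "c"), c("T", "a"))
  cand <- collect_candidates(assoc, "DA", "T")
  fm <- build_feature_matrix(net, cand, assoc)
  expect_true(all(fm$normalized[, "DA"] == 0))  # every gene is a member
})

test_that("feature matrix is invariant to candidate input order", {
  bench <- generate_benchmark(benchmark_config(seed = 4))
  similar <- select_similar_diseases(bench$similarities,
                                     bench$target_disease)
  cand <- suppressWarnings(collect_candidates(bench$associations, similar,
                                              bench$target_disease))
  cand_rev <- cand
  cand_rev$candidate_genes <- rev(cand$candidate_genes)
  a <- build_feature_matrix(bench$network, cand, bench$associations)
  b <- build_feature_matrix(bench$network, cand_rev, bench$associations)
  expect_identical(a, b)
  # every non-degenerate z-scored column has mean 0, sample sd 1
  for (j in seq_len(ncol(a$normalized))) {
    if (a$column_sds[j] > 0) {
      expect_lt(abs(mean(a$normalized[, j])), 1e-9)
      expect_lt(abs(sd(a$normalized[, j]) - 1), 1e-9)
    }
  }
})

test_that("candidate genes missing from the network warn and get sentinels", {
  net <- pathsvm:::new_network("a", "b", 1)
  assoc <- make_assoc(c("DA", "a"), c("DA", "zz"), c("T", "b"))
  cand <- collect_candidates(assoc, "DA", "T")
  expect_warning(fm <- build_feature_matrix(net, cand, assoc),
                 "absent from the")
  expect_true("zz" %in% fm$genes)
})
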
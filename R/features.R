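#' Convert an interaction weight to an edge length
#'
#' The shortest-path machinery interprets an edge's value as a length, so a
#' path's length is the sum of its edge values. Functional-network weights
#' usually encode interaction *strength* (higher = closer), which the
#' default `identity` transform does not invert -- it uses the stated weight
#' directly as the length, matching the feature-extraction example in which
#' a direct neighbor's feature is the interaction strength itself. The
#' alternative transforms are offered for networks where strength should be
#' inverted into distance.
#'
#' @param weight positive numeric vector of interaction weights.
#' @param transform one of `"identity"` (length = weight), `"reciprocal"`
#'   (1/weight), `"neg_log"` (-log(weight), requires weight < 1) or
#'   `"one_minus"` (1 - weight, requires weight < 1).
#' @return positive numeric vector of edge lengths.
#' @export
edge_length <- function(weight,
                        transform = c("identity", "reciprocal",
                                      "neg_log", "one_minus")) {
  transform <- match.arg(transform)
  if (any(weight <= 0))
    stop("edge weight must be positive (offending weight: ",
         fmt_num(weight[which(weight <= 0)[1L]]), ")", call. = FALSE)
  if (transform %in% c("neg_log", "one_minus") && any(weight >= 1)) {
    bad <- weight[which(weight >= 1)[1L]]
    stop("transform '", transform, "' requires weight < 1 to keep edge ",
         "lengths positive (offending weight: ", fmt_num(bad), ")",
         call. = FALSE)
  }
  switch(transform,
         identity   = weight,
         reciprocal = 1 / weight,
         neg_log    = -log(weight),
         one_minus  = 1 - weight)
}

# Adjacency-list form of a gene_network with transformed edge lengths.
# Nodes are in sorted (C-collation) order so index order == lexicographic
# order, which makes which.min tie-breaks deterministic and lexicographic.
network_adjacency <- function(network, transform = "identity") {
  nodes <- network$nodes
  idx <- stats::setNames(seq_along(nodes), nodes)
  len <- edge_length(network$edges$weight, transform)
  ii <- idx[network$edges$from]
  jj <- idx[network$edges$to]
  nbr <- vector("list", length(nodes))
  wts <- vector("list", length(nodes))
  for (e in seq_along(ii)) {
    nbr[[ii[e]]] <- c(nbr[[ii[e]]], jj[e]); wts[[ii[e]]] <- c(wts[[ii[e]]], len[e])
    nbr[[jj[e]]] <- c(nbr[[jj[e]]], ii[e]); wts[[jj[e]]] <- c(wts[[jj[e]]], len[e])
  }
  list(nodes = nodes, idx = idx, nbr = nbr, wts = wts)
}

#' Single-source shortest paths in a weighted gene network
#'
#' Dijkstra's algorithm: every node carries a label `(d_t, p_t)` -- the
#' length of the shortest path from the source and the predecessor on that
#' path. The source starts at `d = 0`, every other node at infinity; the
#' closest unsettled node is settled in turn and its neighbors relaxed via
#' `d_j = min(d_j, d_k + w(k, j))`. Ties among equally close frontier nodes
#' are broken by lexicographic gene id, so the predecessor tree is
#' bit-identical across runs.
#'
#' @param network a `gene_network` object.
#' @param source a gene id present in the network.
#' @param transform edge-length transform, see [edge_length()].
#' @param adjacency optional precomputed [network_adjacency] (internal use,
#'   avoids rebuilding the adjacency list when looping over sources).
#' @return an object of class `shortest_paths`: list with `source`, `d`
#'   (named numeric vector of path lengths, reachable nodes only) and `p`
#'   (named character vector of predecessors; `NA` for the source).
#' @examples
#' net <- example_network()
#' sp <- dijkstra(net, "A")
#' sp$d["D"]  # A-B-C-D, length 4
#' @export
dijkstra <- function(network, source, transform = "identity",
                     adjacency = NULL) {
  adj <- if (is.null(adjacency)) network_adjacency(network, transform)
         else adjacency
  if (!source %in% adj$nodes)
    stop("source gene '", source, "' not in network", call. = FALSE)
  n <- length(adj$nodes)
  d <- rep(Inf, n)
  p <- rep(NA_integer_, n)
  settled <- rep(FALSE, n)
  s <- adj$idx[[source]]
  d[s] <- 0
  repeat {
    # which.min on sorted node order: ties settle the lexicographically
    # smallest gene first
    cand <- which(!settled & is.finite(d))
    if (!length(cand)) break
    k <- cand[which.min(d[cand])]
    settled[k] <- TRUE
    nb <- adj$nbr[[k]]
    if (length(nb)) {
      nd <- d[k] + adj$wts[[k]]
      better <- nd < d[nb]
      if (any(better)) {
        d[nb[better]] <- nd[better]
        p[nb[better]] <- k
      }
    }
  }
  reach <- is.finite(d)
  structure(list(source = source,
                 d = stats::setNames(d[reach], adj$nodes[reach]),
                 p = stats::setNames(
                   ifelse(is.na(p[reach]), NA_character_, adj$nodes[p[reach]]),
                   adj$nodes[reach])),
            class = "shortest_paths")
}

# Tiny worked-example graph used in documentation examples.
#' Small example gene network
#'
#' Four genes on a path A-B-C-D with a longer shortcut A-C; used in examples.
#' @return a `gene_network`.
#' @export
example_network <- function() {
  new_network(c("A", "B", "A", "C"), c("B", "C", "C", "D"),
              c(1, 2, 4, 1))
}

#' Feature of one gene for one disease dimension
#'
#' A gene's feature along a disease dimension is the membership value if
#' the gene is itself one of the disease's known genes, and otherwise the
#' shortest weighted path length from the gene to the nearest of the
#' disease's genes. The default membership value is 0: a member's distance
#' to the disease's gene set is literally zero (the set contains the gene),
#' matching the source label `d = 0` of the shortest-path algorithm. The
#' value 1 -- the convention of reading a member's feature as a full-strength
#' interaction -- is available via `membership_value = 1`. Genes that cannot
#' reach any of the disease's genes get `unreachable` (default `NA`);
#' [build_feature_matrix()] imputes these per column before normalization.
#'
#' @param labels `shortest_paths` from the gene (see [dijkstra()]).
#' @param gene the gene id (must equal `labels$source`).
#' @param disease_genes non-empty character vector of the disease's genes.
#' @param member is `gene` itself one of the disease's genes? Defaults to
#'   testing membership in `disease_genes`.
#' @param membership_value value assigned to direct members; default 0.
#' @param unreachable value when no disease gene is reachable; default `NA`.
#' @return a single numeric feature value.
#' @export
gene_disease_feature <- function(labels, gene, disease_genes,
                                 member = gene %in% disease_genes,
                                 membership_value = 0,
                                 unreachable = NA_real_) {
  stopifnot(inherits(labels, "shortest_paths"), identical(labels$source, gene),
            length(disease_genes) > 0L)
  if (member) return(membership_value)
  dd <- labels$d[names(labels$d) %in% disease_genes]
  if (!length(dd)) unreachable else min(dd)
}

#' Build the disease-distance feature matrix for candidate genes
#'
#' For every candidate gene, runs Dijkstra over the network and records, per
#' similar disease, the membership value (if the gene belongs to that
#' disease) or the shortest-path length to the disease's nearest gene. The
#' target disease's own dimension is excluded: including it would encode the
#' label being predicted. Unreachable entries are imputed per column as 1.5
#' times the column's largest finite value -- farther than anything observed
#' -- before z-scoring; a column with no finite value imputes 0. Each column
#' is then normalized to `(F - mean(F)) / sd(F)` with the sample (n-1)
#' standard deviation; zero-variance columns become all zeros.
#'
#' @param network a `gene_network`.
#' @param candidates a `candidate_set` from [collect_candidates()].
#' @param assoc the `disease_gene_assoc` the candidate set was built from.
#' @param transform edge-length transform, see [edge_length()]; default
#'   `"reciprocal"`, which inverts interaction strength into distance so
#'   that strongly interacting genes are close. `"identity"` (length =
#'   stated weight) is the literal reading of the source algorithm and is
#'   kept available, but on strength-weighted networks it pushes strong
#'   interactors apart.
#' @param membership_value feature value for direct disease membership;
#'   default 0 (see [gene_disease_feature()]).
#' @return an object of class `feature_matrix`: list with `genes` (sorted),
#'   `dimensions` (similar diseases, target excluded), `raw` and
#'   `normalized` matrices, `column_means`, `column_sds`, and the settings
#'   used. Candidate genes absent from the network get all-unreachable rows
#'   (with a warning), not an error.
#' @export
build_feature_matrix <- function(network, candidates, assoc,
                                 transform = "reciprocal",
                                 membership_value = 0) {
  stopifnot(inherits(candidates, "candidate_set"),
            inherits(assoc, "disease_gene_assoc"))
  genes <- sort_ids(candidates$candidate_genes)
  dims <- setdiff(candidates$similar_diseases, candidates$target)
  if (!length(genes)) stop("no candidate genes", call. = FALSE)
  if (!length(dims)) stop("no disease dimensions", call. = FALSE)
  disease_sets <- lapply(dims, function(d) genes_of(assoc, d))
  names(disease_sets) <- dims
  adj <- network_adjacency(network, transform)
  off_network <- setdiff(genes, network$nodes)
  if (length(off_network))
    warning(length(off_network), " candidate gene(s) absent from the ",
            "network; their distances are unreachable: ",
            paste(utils::head(off_network, 5), collapse = ", "),
            if (length(off_network) > 5) ", ..." else "", call. = FALSE)
  raw <- matrix(NA_real_, length(genes), length(dims),
                dimnames = list(genes, dims))
  for (i in seq_along(genes)) {
    g <- genes[i]
    sp <- if (g %in% network$nodes) dijkstra(network, g, transform, adj)
          else NULL
    for (j in seq_along(dims)) {
      set <- disease_sets[[j]]
      if (!length(set)) next  # disease with no genes: stays NA, imputed below
      if (g %in% set) { raw[i, j] <- membership_value; next }
      if (is.null(sp)) next
      dd <- sp$d[names(sp$d) %in% set]
      if (length(dd)) raw[i, j] <- min(dd)
    }
  }
  # per-column unreachable imputation, before normalization
  for (j in seq_len(ncol(raw))) {
    nas <- is.na(raw[, j])
    if (any(nas)) {
      finite <- raw[!nas, j]
      raw[nas, j] <- if (length(finite)) 1.5 * max(finite) else 0
    }
  }
  mu <- colMeans(raw)
  sdv <- apply(raw, 2L, stats::sd)
  normalized <- raw
  for (j in seq_len(ncol(raw))) {
    normalized[, j] <- if (sdv[j] > 0) (raw[, j] - mu[j]) / sdv[j] else 0
  }
  structure(list(genes = genes, dimensions = dims, raw = raw,
                 normalized = normalized, column_means = mu,
                 column_sds = sdv, membership_value = membership_value,
                 transform = transform),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d genes x %d disease dimensions (%s edge lengths)\n",
              length(x$genes), length(x$dimensions), x$transform))
  invisible(x)
}
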
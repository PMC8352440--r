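#' Configuration for the planted-module benchmark generator
#'
#' Describes a synthetic study in which the guilt-by-association signal is
#' planted and therefore recoverable: genes live in network modules
#' (a planted-partition graph, dense within modules and sparse between),
#' each disease draws most of its genes from one module, similar diseases
#' share modules, and a fraction of the target disease's genes is hidden
#' from the emitted associations to play the role of undiscovered disease
#' genes.
#'
#' Defaults describe a small benchmark that a single desk run can evaluate:
#' 4 modules of 50 genes (within-module edge probability 0.3, between 0.02,
#' weights uniform on (0.1, 1)), 8 diseases of 25 genes with 10% of each
#' disease's genes leaking outside its module, and 20% of the target
#' disease's genes held out.
#'
#' @param n_modules number of network modules.
#' @param genes_per_module genes in each module.
#' @param p_within,p_between edge probabilities inside/between modules;
#'   `0 <= p_between < p_within <= 1`.
#' @param weight_low,weight_high uniform edge-weight bounds, positive.
#' @param n_diseases number of diseases (disease `i` is anchored to module
#'   `((i - 1) mod n_modules) + 1`, rotated so disease 1 sits in
#'   `target_module`).
#' @param target_module module index of the target disease.
#' @param genes_per_disease genes drawn per disease.
#' @param leak_fraction fraction of each disease's genes drawn uniformly
#'   from outside its module, in `[0, 1)`.
#' @param holdout_fraction fraction of the target disease's genes hidden
#'   from the emitted associations, in `[0, 1)`.
#' @param seed integer seed.
#' @return a validated list of class `benchmark_config`.
#' @export
benchmark_config <- function(n_modules = 4, genes_per_module = 50,
                             p_within = 0.3, p_between = 0.02,
                             weight_low = 0.1, weight_high = 1,
                             n_diseases = 8, target_module = 1,
                             genes_per_disease = 25, leak_fraction = 0.1,
                             holdout_fraction = 0.2, seed = 7) {
  cfg <- list(n_modules = as.integer(n_modules),
              genes_per_module = as.integer(genes_per_module),
              p_within = p_within, p_between = p_between,
              weight_low = weight_low, weight_high = weight_high,
              n_diseases = as.integer(n_diseases),
              target_module = as.integer(target_module),
              genes_per_disease = as.integer(genes_per_disease),
              leak_fraction = leak_fraction,
              holdout_fraction = holdout_fraction,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_modules >= 1, genes_per_module >= 1, n_diseases >= 1,
              genes_per_disease >= 1,
              target_module >= 1, target_module <= n_modules,
              0 <= p_between, p_between < p_within, p_within <= 1,
              0 < weight_low, weight_low <= weight_high,
              0 <= leak_fraction, leak_fraction < 1,
              0 <= holdout_fraction, holdout_fraction < 1)
  })
  n_in <- ceiling((1 - cfg$leak_fraction) * cfg$genes_per_disease)
  if (n_in > cfg$genes_per_module)
    stop("impossible config: a disease needs ", n_in, " genes from its ",
         "module but modules only hold ", cfg$genes_per_module, " genes",
         call. = FALSE)
  structure(cfg, class = "benchmark_config")
}

# Connected components by breadth-first search over an edge list.
components_of <- function(nodes, from, to) {
  idx <- stats::setNames(seq_along(nodes), nodes)
  adj <- vector("list", length(nodes))
  for (e in seq_along(from)) {
    i <- idx[[from[e]]]; j <- idx[[to[e]]]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  comp <- integer(length(nodes))
  cur <- 0L
  for (s in seq_along(nodes)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  stats::setNames(comp, nodes)
}

#' Generate a planted-module benchmark
#'
#' Draws the planted-partition network, disease gene sets and Jaccard
#' disease similarities described by a [benchmark_config()], hides the
#' configured fraction of target-disease genes, and (optionally) writes the
#' three pipeline input TSVs plus a ground-truth table. The disease
#' similarity between two diseases is the Jaccard overlap of their full
#' (pre-holdout) gene sets -- a monotone stand-in for any external
#' disease-similarity score, unaffected by which target genes happen to be
#' hidden; only positive similarities are emitted (the table is sparse).
#' Held-out genes are preferentially chosen among target genes that a
#' similar disease also carries, so each hidden gene remains discoverable
#' as a candidate.
#'
#' If the largest connected component of the drawn network holds fewer than
#' 90% of the genes, or some held-out target gene falls outside the edge
#' list, the draw is rejected and repeated with the seed incremented (at
#' most 10 attempts), keeping the edge law clean rather than patching
#' connectivity by hand.
#'
#' @param config a `benchmark_config`.
#' @param out_dir if non-`NULL`, directory (created if needed) receiving
#'   `network.tsv`, `associations.tsv`, `similarities.tsv`, `truth.tsv`.
#' @return an object of class `benchmark_truth`: list with `network`,
#'   `associations` (post-holdout), `similarities`, `target_disease`,
#'   `module_of` (named integer), `disease_module` (named integer),
#'   `heldout_targets`, `full_target_genes`, `config`, `seed_used` and
#'   `files` (named paths, or `NULL`).
#' @export
generate_benchmark <- function(config = benchmark_config(), out_dir = NULL) {
  stopifnot(inherits(config, "benchmark_config"))
  for (attempt in 0:9) {
    seed <- config$seed + attempt
    bench <- with_seed(seed, draw_benchmark(config))
    ngenes <- config$n_modules * config$genes_per_module
    comp <- components_of(bench$network$nodes, bench$network$edges$from,
                          bench$network$edges$to)
    if (config$p_between > 0) {
      giant_ok <- max(tabulate(comp)) >= 0.9 * ngenes
    } else {
      # modules are deliberately disconnected; require a giant component
      # inside each module instead
      giant_ok <- all(vapply(seq_len(config$n_modules), function(m) {
        inside <- comp[names(bench$module_of)[bench$module_of == m]]
        inside <- inside[!is.na(inside)]
        length(inside) > 0 &&
          max(tabulate(inside)) >= 0.9 * config$genes_per_module
      }, logical(1)))
    }
    holdout_ok <- all(bench$heldout_targets %in% bench$network$nodes)
    if (giant_ok && holdout_ok) {
      bench$seed_used <- seed
      if (attempt > 0)
        message("benchmark regenerated with seed ", seed,
                " (earlier draw failed the giant-component check)")
      if (!is.null(out_dir)) bench <- write_benchmark(bench, out_dir)
      return(bench)
    }
  }
  stop("failed to draw a benchmark with a giant component holding 90% of ",
       "genes in 10 attempts; increase p_within or module size",
       call. = FALSE)
}

# One seeded draw; RNG state is managed by the caller.
draw_benchmark <- function(cfg) {
  ngenes <- cfg$n_modules * cfg$genes_per_module
  genes <- sprintf("g%04d", seq_len(ngenes))
  module_of <- stats::setNames(rep(seq_len(cfg$n_modules),
                                   each = cfg$genes_per_module), genes)

  # planted-partition edges over all unordered pairs
  pairs_i <- rep(seq_len(ngenes - 1L), times = (ngenes - 1L):1L)
  pairs_j <- unlist(lapply(seq_len(ngenes - 1L), function(i) (i + 1L):ngenes))
  same <- module_of[pairs_i] == module_of[pairs_j]
  p <- ifelse(same, cfg$p_within, cfg$p_between)
  keep <- stats::runif(length(p)) < p
  from <- genes[pairs_i[keep]]
  to <- genes[pairs_j[keep]]
  w <- stats::runif(sum(keep), cfg$weight_low, cfg$weight_high)
  network <- new_network(from, to, w)

  # diseases anchored to modules, disease 1 = target in target_module
  diseases <- sprintf("D%d", seq_len(cfg$n_diseases))
  disease_module <- stats::setNames(
    ((seq_len(cfg$n_diseases) - 1L + cfg$target_module - 1L) %% cfg$n_modules) + 1L,
    diseases)
  target <- diseases[1L]

  n_in <- ceiling((1 - cfg$leak_fraction) * cfg$genes_per_disease)
  n_out <- cfg$genes_per_disease - n_in
  gene_sets <- lapply(diseases, function(d) {
    m <- disease_module[[d]]
    inside <- genes[module_of == m]
    outside <- genes[module_of != m]
    picked <- sample(inside, n_in)
    if (n_out > 0L) picked <- c(picked, sample(outside, n_out))
    sort_ids(picked)
  })
  names(gene_sets) <- diseases

  # Sparse Jaccard similarity on the full gene sets, computed before the
  # holdout: similarity emulates an external disease-relatedness source and
  # must not be eroded by hiding target genes (which would sever exactly the
  # links that make hidden genes discoverable).
  da <- character(0); db <- character(0); sv <- numeric(0)
  for (i in seq_len(cfg$n_diseases - 1L)) {
    for (j in (i + 1L):cfg$n_diseases) {
      inter <- length(intersect(gene_sets[[i]], gene_sets[[j]]))
      if (inter == 0L) next
      jac <- inter / length(union(gene_sets[[i]], gene_sets[[j]]))
      da <- c(da, diseases[i]); db <- c(db, diseases[j]); sv <- c(sv, jac)
    }
  }

  full_target <- gene_sets[[target]]
  n_hold <- floor(cfg$holdout_fraction * length(full_target))
  # Hold out target genes that a positively-similar disease also carries: a
  # hidden "novel" gene must remain reachable as a candidate (via a similar
  # disease) or recovery is undefined by construction. Top up from the rest
  # only if too few target genes are shared.
  sim_diseases <- union(db[da == target], da[db == target])
  shared <- intersect(full_target,
                      unlist(gene_sets[sim_diseases], use.names = FALSE))
  heldout <- character(0)
  if (n_hold > 0L) {
    heldout <- sample(shared, min(n_hold, length(shared)))
    if (length(heldout) < n_hold)
      heldout <- c(heldout, sample(setdiff(full_target, heldout),
                                   n_hold - length(heldout)))
    heldout <- sort_ids(heldout)
  }
  gene_sets[[target]] <- setdiff(full_target, heldout)

  entries <- data.frame(
    disease_id = rep(diseases, lengths(gene_sets)),
    gene_id = unlist(gene_sets, use.names = FALSE),
    stringsAsFactors = FALSE)
  associations <- new_associations(entries)
  similarities <- data.frame(disease_a = da, disease_b = db, similarity = sv,
                             stringsAsFactors = FALSE)
  swap <- similarities$disease_b < similarities$disease_a
  tmp <- similarities$disease_a[swap]
  similarities$disease_a[swap] <- similarities$disease_b[swap]
  similarities$disease_b[swap] <- tmp
  similarities <- similarities[
    order_ids(paste(similarities$disease_a, similarities$disease_b,
                    sep = "\t")), , drop = FALSE]
  rownames(similarities) <- NULL
  class(similarities) <- c("disease_similarity", "data.frame")

  structure(list(network = network, associations = associations,
                 similarities = similarities, target_disease = target,
                 module_of = module_of, disease_module = disease_module,
                 heldout_targets = heldout, full_target_genes = full_target,
                 config = cfg, seed_used = NA_integer_, files = NULL),
            class = "benchmark_truth")
}

# Emit the four benchmark TSVs; returns the truth object with file paths.
write_benchmark <- function(bench, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- c(network = file.path(out_dir, "network.tsv"),
             associations = file.path(out_dir, "associations.tsv"),
             similarities = file.path(out_dir, "similarities.tsv"),
             truth = file.path(out_dir, "truth.tsv"))
  write_network(bench$network, files[["network"]])
  write_associations(bench$associations, files[["associations"]])
  write_similarities(bench$similarities, files[["similarities"]])
  genes <- names(bench$module_of)
  writeLines(c("gene_id\tmodule\theldout_target",
               paste(genes, bench$module_of,
                     as.integer(genes %in% bench$heldout_targets),
                     sep = "\t")),
             files[["truth"]], useBytes = TRUE)
  bench$files <- files
  bench
}

#' @export
print.benchmark_truth <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0(
    "Planted-module benchmark (seed %d): %d genes in %d modules, ",
    "%d edges,\n  %d diseases, target '%s' (module %d), %d held-out ",
    "target genes\n"),
    x$seed_used, cfg$n_modules * cfg$genes_per_module, cfg$n_modules,
    nrow(x$network$edges), cfg$n_diseases, x$target_disease,
    x$disease_module[[x$target_disease]], length(x$heldout_targets)))
  invisible(x)
}
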
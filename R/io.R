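#' @title Tabular input/output for the prioritization pipeline
#'
#' @description
#' Readers and writers for the three tab-separated inputs the pipeline
#' consumes -- disease--disease similarities, disease--gene associations and
#' a weighted undirected gene interaction network -- plus the pipeline's own
#' outputs (feature matrices, rankings, fitted model files). All formats are
#' UTF-8 TSV with a literal tab separator; lines starting with `#` are
#' skipped; a header line is optional and auto-detected. Gene and disease
#' identifiers are opaque, case-sensitive strings: no identifier mapping is
#' attempted.
#'
#' @name pathsvm-io
NULL

# Read non-comment, non-blank lines of a TSV, keeping original line numbers.
read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  list(lines = raw[keep], lineno = which(keep))
}

split_fields <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  # strsplit drops trailing empty fields; restore them so blank last columns
  # are caught by validation rather than shifting the field count
  trail <- attr(regexpr("\t*$", line), "match.length")
  c(f, character(trail))
}

is_number <- function(x) !is.na(suppressWarnings(as.numeric(x)))

#' Read a disease-disease similarity table
#'
#' Parses a TSV with columns `disease_a`, `disease_b`, `similarity`
#' (a real number in \[0, 1\]). The table may be sparse: an absent pair is
#' treated downstream as similarity 0. A header line is auto-detected (third
#' field not numeric).
#'
#' @param path path to a TSV file.
#' @return a data frame of class `disease_similarity` with columns
#'   `disease_a`, `disease_b`, `similarity`; one row per unordered pair.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines("IBD\tD1\t0.08", tf)
#' read_similarities(tf)
#' @export
read_similarities <- function(path) {
  tl <- read_tsv_lines(path)
  recs <- vector("list", length(tl$lines))
  start <- 1L
  if (length(tl$lines) >= 1L) {
    f <- split_fields(tl$lines[[1L]])
    if (length(f) >= 3L && !is_number(f[3L])) start <- 2L  # header
  }
  n <- 0L
  for (i in seq_along(tl$lines)) {
    if (i < start) next
    f <- split_fields(tl$lines[[i]])
    ln <- tl$lineno[[i]]
    if (length(f) < 3L)
      stop_parse(path, ln, "expected 3 tab-separated fields (disease_a, disease_b, similarity)")
    if (!nzchar(f[1L]) || !nzchar(f[2L]))
      stop_parse(path, ln, "blank disease identifier")
    s <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s)) stop_parse(path, ln, paste0("similarity not numeric: '", f[3L], "'"))
    if (s < 0 || s > 1)
      stop_parse(path, ln, sprintf("similarity %g outside [0, 1]", s))
    n <- n + 1L
    recs[[n]] <- c(f[1L], f[2L], f[3L])
  }
  if (n == 0L) {
    out <- data.frame(disease_a = character(), disease_b = character(),
                      similarity = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("disease_similarity", "data.frame")
    return(out)
  }
  m <- do.call(rbind, recs[seq_len(n)])
  out <- data.frame(disease_a = m[, 1L], disease_b = m[, 2L],
                    similarity = as.numeric(m[, 3L]), stringsAsFactors = FALSE)
  # canonicalize unordered pairs, then check duplicates
  swap <- out$disease_b < out$disease_a
  tmp <- out$disease_a[swap]
  out$disease_a[swap] <- out$disease_b[swap]
  out$disease_b[swap] <- tmp
  key <- paste(out$disease_a, out$disease_b, sep = "\t")
  if (anyDuplicated(key)) {
    for (k in unique(key[duplicated(key)])) {
      vals <- unique(out$similarity[key == k])
      if (length(vals) > 1L)
        stop("duplicate disease pair with conflicting similarities: ",
             gsub("\t", " / ", k), call. = FALSE)
    }
    out <- out[!duplicated(key), , drop = FALSE]
  }
  out <- out[order_ids(paste(out$disease_a, out$disease_b, sep = "\t")), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("disease_similarity", "data.frame")
  out
}

#' Write a disease-disease similarity table
#'
#' @param sim a `disease_similarity` data frame (see [read_similarities()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_similarities <- function(sim, path) {
  lines <- c("disease_a\tdisease_b\tsimilarity",
             paste(sim$disease_a, sim$disease_b, fmt_num(sim$similarity),
                   sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read disease-gene associations
#'
#' Parses a two-column TSV of `(disease_id, gene_id)` pairs, in the style of
#' a DisGeNET export. Duplicate lines collapse to a single membership. The
#' returned object keeps both the number of distinct (disease, gene) entries
#' and the number of unique genes, mirroring the distinction between total
#' association entries and the unique candidate pool they induce.
#'
#' @param path path to a TSV file. A header line whose fields are
#'   `disease_id`/`gene_id` (any case) is skipped.
#' @return an object of class `disease_gene_assoc`: a list with `entries`
#'   (deduplicated data frame of `disease_id`, `gene_id`), `entry_count` and
#'   `unique_gene_count`.
#' @seealso [genes_of()]
#' @export
read_associations <- function(path) {
  tl <- read_tsv_lines(path)
  start <- 1L
  if (length(tl$lines) >= 1L) {
    f <- tolower(split_fields(tl$lines[[1L]]))
    if (length(f) >= 2L && f[1L] %in% c("disease_id", "disease") &&
        f[2L] %in% c("gene_id", "gene"))
      start <- 2L
  }
  ds <- character(0); gs <- character(0)
  for (i in seq_along(tl$lines)) {
    if (i < start) next
    f <- split_fields(tl$lines[[i]])
    ln <- tl$lineno[[i]]
    if (length(f) < 2L)
      stop_parse(path, ln, "expected 2 tab-separated fields (disease_id, gene_id)")
    if (!nzchar(f[1L])) stop_parse(path, ln, "blank disease identifier")
    if (!nzchar(f[2L])) stop_parse(path, ln, "blank gene identifier")
    ds <- c(ds, f[1L]); gs <- c(gs, f[2L])
  }
  new_associations(data.frame(disease_id = ds, gene_id = gs,
                              stringsAsFactors = FALSE))
}

# Construct a disease_gene_assoc from a (possibly duplicated) entries frame.
new_associations <- function(entries) {
  key <- paste(entries$disease_id, entries$gene_id, sep = "\t")
  entries <- entries[!duplicated(key), , drop = FALSE]
  entries <- entries[order_ids(paste(entries$disease_id, entries$gene_id,
                                     sep = "\t")), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(entries = entries,
                 entry_count = nrow(entries),
                 unique_gene_count = length(unique(entries$gene_id))),
            class = "disease_gene_assoc")
}

#' Genes associated with a disease
#'
#' @param assoc a `disease_gene_assoc` object.
#' @param disease a disease identifier.
#' @return character vector of gene ids (duplicate-free, sorted); empty if
#'   the disease has no recorded associations.
#' @export
genes_of <- function(assoc, disease) {
  stopifnot(inherits(assoc, "disease_gene_assoc"))
  sort_ids(assoc$entries$gene_id[assoc$entries$disease_id == disease])
}

#' @export
print.disease_gene_assoc <- function(x, ...) {
  cat(sprintf(
    "Disease-gene associations: %d diseases, %d entries, %d unique genes\n",
    length(unique(x$entries$disease_id)), x$entry_count,
    x$unique_gene_count))
  invisible(x)
}

#' Write disease-gene associations
#'
#' @param assoc a `disease_gene_assoc` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(assoc, path) {
  lines <- c("disease_id\tgene_id",
             paste(assoc$entries$disease_id, assoc$entries$gene_id, sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a weighted gene interaction network
#'
#' Parses a three-column TSV edge list `(gene_a, gene_b, weight)` in the
#' style of a functional gene network export, where the weight is a positive
#' interaction strength. The graph is undirected: a pair listed in both
#' orientations with the same weight collapses to one edge; conflicting
#' weights for the same pair, self-loops and non-positive weights are
#' errors.
#'
#' @param path path to a TSV file; header auto-detected (third field not
#'   numeric).
#' @return an object of class `gene_network`: a list with `nodes` (sorted
#'   character vector) and `edges` (data frame `from`, `to`, `weight` with
#'   `from < to`).
#' @export
read_network <- function(path) {
  tl <- read_tsv_lines(path)
  start <- 1L
  if (length(tl$lines) >= 1L) {
    f <- split_fields(tl$lines[[1L]])
    if (length(f) >= 3L && !is_number(f[3L])) start <- 2L
  }
  a <- character(0); b <- character(0); w <- numeric(0)
  for (i in seq_along(tl$lines)) {
    if (i < start) next
    f <- split_fields(tl$lines[[i]])
    ln <- tl$lineno[[i]]
    if (length(f) < 3L)
      stop_parse(path, ln, "expected 3 tab-separated fields (gene_a, gene_b, weight)")
    if (!nzchar(f[1L]) || !nzchar(f[2L]))
      stop_parse(path, ln, "blank gene identifier")
    wt <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(wt)) stop_parse(path, ln, paste0("weight not numeric: '", f[3L], "'"))
    if (wt <= 0) stop_parse(path, ln, sprintf("weight must be positive, got %g", wt))
    if (f[1L] == f[2L])
      stop_parse(path, ln, paste0("self-loop on gene '", f[1L], "'"))
    a <- c(a, f[1L]); b <- c(b, f[2L]); w <- c(w, wt)
  }
  new_network(a, b, w)
}

# Construct a gene_network from parallel edge vectors, validating dedupe.
new_network <- function(a, b, w) {
  swap <- b < a
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  key <- paste(a, b, sep = "\t")
  if (anyDuplicated(key)) {
    for (k in unique(key[duplicated(key)])) {
      vals <- unique(w[key == k])
      if (length(vals) > 1L)
        stop("conflicting duplicate edge: ", gsub("\t", " -- ", k), call. = FALSE)
    }
    keep <- !duplicated(key)
    a <- a[keep]; b <- b[keep]; w <- w[keep]
  }
  o <- order_ids(paste(a, b, sep = "\t"))
  edges <- data.frame(from = a[o], to = b[o], weight = w[o],
                      stringsAsFactors = FALSE)
  structure(list(nodes = sort_ids(c(a, b)), edges = edges),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("Gene network: %d nodes, %d weighted undirected edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Write a weighted gene network
#'
#' @param network a `gene_network` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  lines <- c("gene_a\tgene_b\tweight",
             paste(network$edges$from, network$edges$to,
                   fmt_num(network$edges$weight), sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a feature matrix to TSV
#'
#' First column `gene_id`, one column per similar-disease dimension with the
#' disease id as header. By default the z-scored matrix is written.
#'
#' @param fm a `feature_matrix` object (see [build_feature_matrix()]).
#' @param path output file path.
#' @param which `"normalized"` (default) or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path, which = c("normalized", "raw")) {
  which <- match.arg(which)
  m <- fm[[which]]
  header <- paste(c("gene_id", fm$dimensions), collapse = "\t")
  body <- vapply(seq_along(fm$genes), function(i)
    paste(c(fm$genes[i], fmt_num(m[i, ])), collapse = "\t"), character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read a feature matrix from TSV
#'
#' @param path a TSV written by [write_feature_matrix()].
#' @return a numeric matrix, genes in rows (rownames), disease dimensions in
#'   columns (colnames).
#' @export
read_feature_matrix <- function(path) {
  tl <- read_tsv_lines(path)
  if (length(tl$lines) < 1L) stop("empty feature matrix file: ", path, call. = FALSE)
  header <- split_fields(tl$lines[[1L]])
  dims <- header[-1L]
  rows <- lapply(tl$lines[-1L], split_fields)
  genes <- vapply(rows, `[`, character(1), 1L)
  m <- matrix(NA_real_, length(rows), length(dims),
              dimnames = list(genes, dims))
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]][-1L]))
    if (length(v) != length(dims) || anyNA(v))
      stop_parse(path, tl$lineno[[i + 1L]], "malformed feature row")
    m[i, ] <- v
  }
  m
}

#' Write a candidate-gene ranking to TSV
#'
#' @param ranking a `gene_ranking` object (see [rank_candidates()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  lines <- c(sprintf("# threshold\t%s", fmt_num(ranking$threshold)),
             "gene_id\tscore\trank",
             paste(ranking$entries$gene, fmt_num(ranking$entries$score),
                   ranking$entries$rank, sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a fitted least-squares SVM to a key-value text file
#'
#' Stores the kernel width, regularization, bias, training gene ids, labels
#' and dual coefficients. The training feature vectors themselves are not
#' duplicated: [read_lssvm()] reconstructs them from the feature matrix the
#' model was trained on.
#'
#' @param model an `lssvm` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lssvm <- function(model, path) {
  stopifnot(inherits(model, "lssvm"))
  ids <- rownames(model$x)
  if (is.null(ids)) stop("model has no training gene ids (unnamed rows); ",
                         "train on a feature matrix with rownames", call. = FALSE)
  lines <- c("format\tpathsvm-lssvm-1",
             paste0("sigma\t", fmt_num(model$sigma)),
             paste0("gamma\t", fmt_num(model$gamma)),
             paste0("b\t", fmt_num(model$b)),
             paste0("n\t", nrow(model$x)),
             paste(c("genes", ids), collapse = "\t"),
             paste(c("labels", fmt_num(model$y)), collapse = "\t"),
             paste(c("a", fmt_num(model$a)), collapse = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a fitted least-squares SVM from a key-value text file
#'
#' @param path file written by [write_lssvm()].
#' @param features numeric matrix with gene rownames containing (at least)
#'   the training genes' feature rows, e.g. from [read_feature_matrix()].
#' @return an `lssvm` object.
#' @export
read_lssvm <- function(path, features) {
  tl <- read_tsv_lines(path)
  kv <- lapply(tl$lines, split_fields)
  names(kv) <- vapply(kv, `[`, character(1), 1L)
  if (!identical(kv$format[2L], "pathsvm-lssvm-1"))
    stop("not a pathsvm model file: ", path, call. = FALSE)
  ids <- kv$genes[-1L]
  missing <- setdiff(ids, rownames(features))
  if (length(missing))
    stop("training genes absent from feature matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  structure(list(x = features[ids, , drop = FALSE],
                 y = as.numeric(kv$labels[-1L]),
                 a = as.numeric(kv$a[-1L]),
                 b = as.numeric(kv$b[2L]),
                 sigma = as.numeric(kv$sigma[2L]),
                 gamma = as.numeric(kv$gamma[2L]),
                 call = NULL),
            class = "lssvm")
}
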
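#' Run the full prioritization pipeline for one target disease
#'
#' Convenience wrapper chaining the individual steps: select diseases
#' similar to the target, pool their genes into the candidate set, build
#' the shortest-path feature matrix, draw a balanced negative sample,
#' cross-validate the LS-SVM, train the final model on all labeled genes,
#' and rank the remaining unlabeled candidates.
#'
#' @param network a `gene_network` (see [read_network()]).
#' @param associations a `disease_gene_assoc` (see [read_associations()]).
#' @param similarities a `disease_similarity` table
#'   (see [read_similarities()]).
#' @param target target disease identifier.
#' @param min_similarity similarity threshold for
#'   [select_similar_diseases()].
#' @param transform edge-length transform (see [edge_length()]).
#' @param gamma,sigma LS-SVM hyperparameters (see [lssvm()]).
#' @param k cross-validation folds.
#' @param threshold nomination threshold on the decision score.
#' @param seed integer seed driving the fold split and negative sampling.
#' @param stratified use stratified folds (see [cross_validate()]).
#' @return list with `candidates`, `features`, `positives`, `negatives`,
#'   `cv` (a `pathsvm_cv`), `model` (the final `lssvm`) and `ranking`
#'   (a `gene_ranking`).
#' @examples
#' bench <- generate_benchmark(benchmark_config(seed = 7))
#' res <- run_pipeline(bench$network, bench$associations,
#'                     bench$similarities, bench$target_disease, seed = 7)
#' res$cv
#' @export
run_pipeline <- function(network, associations, similarities, target,
                         min_similarity = 0, transform = "reciprocal",
                         gamma = 1, sigma = NULL, k = 10, threshold = 0,
                         seed = 1, stratified = FALSE) {
  similar <- select_similar_diseases(similarities, target, min_similarity)
  cand <- collect_candidates(associations, similar, target)
  fm <- build_feature_matrix(network, cand, associations,
                             transform = transform)
  positives <- intersect(cand$positive_genes, fm$genes)
  if (!length(positives))
    stop("target disease '", target, "' has no known genes inside the ",
         "candidate pool", call. = FALSE)
  negatives <- sample_negatives(fm$genes, positives, seed = seed)
  cv <- cross_validate(fm, positives, negatives, k = k, gamma = gamma,
                       sigma = sigma, seed = seed, stratified = stratified)
  X <- fm$normalized
  labeled <- c(positives, negatives)
  y <- ifelse(labeled %in% positives, 1, -1)
  model <- lssvm(X[labeled, , drop = FALSE], y, gamma = gamma, sigma = sigma)
  ranking <- rank_candidates(model, fm, labeled, threshold = threshold)
  list(candidates = cand, features = fm, positives = positives,
       negatives = negatives, cv = cv, model = model, ranking = ranking)
}
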
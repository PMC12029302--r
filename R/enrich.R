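#' Risk-gene enrichment fold of a selected subset
#'
#' The enrichment fold of a selected subset relative to a population is
#' `(L / M) / (K / N)`, where N is the population size, K the number of
#' population elements in the category of interest (risk genes), M the
#' subset size and L the number of subset elements in the category. A fold
#' of 1 means the subset carries risk genes at exactly the population rate.
#'
#' @param L risk genes in the subset.
#' @param M subset size (> 0).
#' @param K risk genes in the population (> 0).
#' @param N population size (> 0).
#' @return The enrichment fold, a non-negative number.
#' @examples
#' enrichment_fold(2, 4, 10, 100)  # 5
#' @export
enrichment_fold <- function(L, M, K, N) {
  for (nm in c("L", "M", "K", "N")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0)
      stop("enrichment_fold: ", nm, " must be a single non-negative count")
  }
  if (M == 0) stop("enrichment_fold: zero denominator M (empty subset)")
  if (K == 0) stop("enrichment_fold: zero denominator K (no risk genes in population)")
  if (N == 0) stop("enrichment_fold: zero denominator N (empty population)")
  if (L > M) stop("enrichment_fold: L exceeds M")
  if (K > N) stop("enrichment_fold: K exceeds N")
  (L / M) / (K / N)
}

#' Screen bi-clusters by risk-gene enrichment and extract candidate drugs
#'
#' Scores every bi-cluster's attached gene set for risk-gene enrichment
#' against a gene population (normally the full gene universe of the
#' drug-gene network, so that cluster genes are a selected subset of it),
#' then collects the primary nodes (drugs) of all passing clusters.
#'
#' @param biclusters list of `bicluster` objects.
#' @param risk a [risk_gene_set()] (or character vector of gene ids).
#' @param population character vector: the gene universe. `K` is the number
#'   of risk genes inside this universe.
#' @param threshold enrichment-fold cut-off (default 2.75).
#' @param inclusive if `TRUE` (default) clusters pass at fold >= threshold;
#'   if `FALSE` the comparison is strict.
#' @return A list with `results`, a data frame (`cluster_id`, `L`, `M`,
#'   `K`, `N`, `enrichment_fold`, `passed`; clusters with no attached gene
#'   get fold `NA` and fail), and `candidates`, the sorted union of primary
#'   nodes over passing clusters.
#' @export
screen_clusters <- function(biclusters, risk, population, threshold = 2.75,
                            inclusive = TRUE) {
  if (inherits(risk, "risk_gene_set")) risk <- risk$genes
  risk <- unique(as.character(risk))
  population <- unique(as.character(population))
  if (!length(population)) stop("screen_clusters: empty population")
  N <- length(population)
  K <- length(intersect(risk, population))
  rows <- lapply(biclusters, function(bc) {
    stopifnot(inherits(bc, "bicluster"))
    genes <- bc$attached_nodes
    M <- length(genes)
    L <- length(intersect(genes, risk))
    fold <- if (M > 0 && K > 0) enrichment_fold(L, M, K, N) else NA_real_
    data.frame(cluster_id = bc$cluster_id, L = L, M = M, K = K, N = N,
               enrichment_fold = fold,
               passed = !is.na(fold) &&
                 (if (inclusive) fold >= threshold else fold > threshold))
  })
  results <- do.call(rbind, c(rows, list(
    data.frame(cluster_id = integer(), L = integer(), M = integer(),
               K = integer(), N = integer(), enrichment_fold = numeric(),
               passed = logical()))))
  rownames(results) <- NULL
  drugs <- unlist(lapply(biclusters[which(results$passed)], `[[`, "primary_nodes"),
                  use.names = FALSE)
  list(results = results, candidates = sort(unique(drugs)))
}
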
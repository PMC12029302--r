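#' Run the full drug-repurposing workflow
#'
#' Executes both evidence channels end to end and joins them:
#' \enumerate{
#'   \item bi-cluster the drug-gene network (fold, density clustering,
#'     attachment) and screen the bi-clusters by risk-gene enrichment fold,
#'     giving one candidate drug set;
#'   \item screen diseases by gene-set similarity to the focal disease and
#'     collect every drug reaching a passing disease through at least one
#'     gene path in the tripartite network, giving a second candidate set;
#'   \item intersect the two sets and rank the surviving drugs by
#'     `alpha * DCS + beta * GAS`.
#' }
#'
#' @param dgi drug-gene `bipartite_network` (drugs on side a).
#' @param dga disease-gene `bipartite_network` (diseases on side a).
#' @param risk a [risk_gene_set()] or character vector of risk-gene ids.
#' @param focal focal disease: an id present in `dga`, or a gene set;
#'   defaults to the risk genes themselves.
#' @param fold_params,cluster_params stage parameters, see [fold_params()]
#'   and [cluster_params()].
#' @param enrich_threshold enrichment-fold cut-off (default 2.75).
#' @param enrich_inclusive pass clusters at fold >= threshold (default).
#' @param sim_threshold disease-similarity cut-off (default 0.95).
#' @param measure disease-similarity measure (default overlap coefficient).
#' @param alpha,beta total-score weights (default 1, 1).
#' @return A list of class `repurposing_result`: `biclusters`,
#'   `enrichment` (results + candidates), `similar_diseases`,
#'   `drugs_by_similarity`, `candidates` (the intersection), `ranking`,
#'   and `counts`, a stage-by-stage tally of the funnel.
#' @export
run_pipeline <- function(dgi, dga, risk, focal = NULL,
                         fold_params = repnet::fold_params(),
                         cluster_params = repnet::cluster_params(),
                         enrich_threshold = 2.75, enrich_inclusive = TRUE,
                         sim_threshold = 0.95,
                         measure = c("overlap", "jaccard", "dice"),
                         alpha = 1, beta = 1) {
  measure <- match.arg(measure)
  risk_genes <- if (inherits(risk, "risk_gene_set")) risk$genes else
    unique(as.character(risk))
  if (is.null(focal)) focal <- risk_genes

  bcs <- bicluster_pipeline(dgi, "a", fold_params, cluster_params)
  enr <- screen_clusters(bcs, risk_genes, population = dgi$side_b,
                         threshold = enrich_threshold,
                         inclusive = enrich_inclusive)

  sim <- screen_diseases(dga, focal, sim_threshold, measure)
  tri <- tripartite_network(dgi, dga)
  drugs_sim <- character()
  if (nrow(sim) > 0) {
    m_all <- build_drug_disease_matrix(tri, tri$dgi$side_a, sim$disease_id)
    drugs_sim <- rownames(m_all)[rowSums(m_all) > 0]
  }

  cand <- intersect_candidates(enr$candidates, drugs_sim)
  ranking <- if (length(cand) && nrow(sim))
    score_drugs(tri, cand, sim$disease_id, alpha, beta)
  else
    data.frame(drug_id = character(), dcs = integer(), gas = integer(),
               total = numeric(), rank = integer(), stringsAsFactors = FALSE)

  counts <- list(
    n_drugs = length(dgi$side_a), n_genes = length(dgi$side_b),
    n_dgi_edges = n_edges(dgi),
    n_diseases = length(dga$side_a), n_dga_edges = n_edges(dga),
    n_biclusters = length(bcs),
    n_enriched_clusters = sum(enr$results$passed),
    n_drugs_by_biclustering = length(enr$candidates),
    n_similar_diseases = nrow(sim),
    n_drugs_by_similarity = length(drugs_sim),
    n_intersection = length(cand))

  structure(list(biclusters = bcs, enrichment = enr, similar_diseases = sim,
                 drugs_by_similarity = sort(drugs_sim), candidates = cand,
                 ranking = ranking, counts = counts,
                 parameters = list(fold = fold_params, cluster = cluster_params,
                                   enrich_threshold = enrich_threshold,
                                   enrich_inclusive = enrich_inclusive,
                                   sim_threshold = sim_threshold,
                                   measure = measure, alpha = alpha,
                                   beta = beta)),
            class = "repurposing_result")
}

#' @export
print.repurposing_result <- function(x, ...) {
  c_ <- x$counts
  cat("drug-repurposing pipeline result\n")
  cat(sprintf("  DGI: %d drugs, %d genes, %d edges; DGA: %d diseases, %d edges\n",
              c_$n_drugs, c_$n_genes, c_$n_dgi_edges, c_$n_diseases,
              c_$n_dga_edges))
  cat(sprintf("  bi-clusters: %d (%d enriched) -> %d drugs\n",
              c_$n_biclusters, c_$n_enriched_clusters,
              c_$n_drugs_by_biclustering))
  cat(sprintf("  similar diseases: %d -> %d drugs\n",
              c_$n_similar_diseases, c_$n_drugs_by_similarity))
  cat(sprintf("  intersection: %d candidate drugs\n", c_$n_intersection))
  if (nrow(x$ranking))
    print(utils::head(x$ranking, 10))
  invisible(x)
}

#' Write a provenance report of a pipeline run as JSON
#'
#' Records the parameters, the stage-by-stage counts of the candidate
#' funnel, and the ranked candidates.
#'
#' @param result a `repurposing_result` from [run_pipeline()].
#' @param path output path.
#' @export
write_provenance <- function(result, path) {
  stopifnot(inherits(result, "repurposing_result"))
  p <- result$parameters
  jsonlite::write_json(
    list(parameters = list(
           tanimoto_min = p$fold$tanimoto_min,
           relation_min = p$fold$relation_min,
           density_min = p$cluster$density_min,
           cluster_property_min = p$cluster$cluster_property_min,
           attachment_min = p$cluster$attachment_min,
           enrich_threshold = p$enrich_threshold,
           enrich_inclusive = p$enrich_inclusive,
           sim_threshold = p$sim_threshold,
           measure = p$measure, alpha = p$alpha, beta = p$beta),
         counts = result$counts,
         ranking = result$ranking),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
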
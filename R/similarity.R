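#' Gene-set similarity between two diseases
#'
#' Explicit set-overlap measures on two gene sets, each in \[0, 1\] with 1
#' for identical sets:
#' overlap coefficient |A ∩ B| / min(|A|, |B|) (default), Jaccard
#' |A ∩ B| / |A ∪ B|, and Dice 2 |A ∩ B| / (|A| + |B|). For any pair,
#' jaccard <= dice <= overlap.
#'
#' @param set_a,set_b non-empty character vectors of gene ids.
#' @param measure `"overlap"`, `"jaccard"` or `"dice"`.
#' @return Similarity in \[0, 1\].
#' @export
gene_set_similarity <- function(set_a, set_b,
                                measure = c("overlap", "jaccard", "dice")) {
  measure <- match.arg(measure)
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  if (!length(set_a) || !length(set_b))
    stop("gene_set_similarity: gene sets must be non-empty")
  inter <- length(intersect(set_a, set_b))
  switch(measure,
         overlap = inter / min(length(set_a), length(set_b)),
         jaccard = inter / length(union(set_a, set_b)),
         dice = 2 * inter / (length(set_a) + length(set_b)))
}

#' Gene sets per disease from a disease-gene network
#'
#' @param dga a `bipartite_network` with diseases on side a and genes on
#'   side b.
#' @return A named list of character gene vectors, one per disease.
#' @export
disease_gene_sets <- function(dga) {
  stopifnot(inherits(dga, "bipartite_network"))
  sets <- split(dga$edges$b, factor(dga$edges$a, levels = dga$side_a))
  lapply(sets, unique)
}

#' Similarity of every disease to a focal gene set
#'
#' Computes the gene-set similarity of each disease in the network to a
#' focal disease. The focal disease may be named by id (its gene set is
#' taken from the network and the disease itself is excluded from the
#' table) or supplied directly as a gene set — e.g. an externally curated
#' risk-gene list for a disease absent from the network.
#'
#' @param dga a `bipartite_network` (diseases on side a, genes on side b).
#' @param focal a single disease id present in `dga`, or a character vector
#'   of two or more gene ids used as the focal gene set.
#' @param measure similarity measure, see [gene_set_similarity()].
#' @return A data frame of class `similarity_table` with columns
#'   `disease_id`, `similarity`, `n_shared_genes`, sorted by similarity
#'   descending (ties lexicographic); attributes `focal`, `measure`.
#' @export
disease_similarity <- function(dga, focal,
                               measure = c("overlap", "jaccard", "dice")) {
  measure <- match.arg(measure)
  sets <- disease_gene_sets(dga)
  focal_id <- NA_character_
  if (length(focal) == 1 && focal %in% names(sets)) {
    focal_id <- focal
    focal_genes <- sets[[focal]]
    sets <- sets[setdiff(names(sets), focal_id)]
  } else if (length(focal) >= 2) {
    focal_genes <- unique(as.character(focal))
  } else {
    stop("focal disease '", focal, "' absent from the network and no ",
         "explicit gene set given")
  }
  if (!length(focal_genes)) stop("focal gene set is empty")
  sim <- vapply(sets, gene_set_similarity, 0, set_b = focal_genes,
                measure = measure)
  shared <- vapply(sets, function(g) length(intersect(g, focal_genes)), 1L)
  out <- data.frame(disease_id = names(sets), similarity = unname(sim),
                    n_shared_genes = unname(shared), stringsAsFactors = FALSE)
  out <- out[order(-out$similarity, out$disease_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, focal = if (is.na(focal_id)) focal_genes else focal_id,
            measure = measure, class = c("similarity_table", "data.frame"))
}

#' Screen diseases by similarity to the focal disease
#'
#' Keeps the diseases whose gene-set similarity to the focal disease
#' reaches the threshold (inclusive). The focal disease itself is never
#' returned.
#'
#' @inheritParams disease_similarity
#' @param threshold similarity cut-off in \[0, 1\] (default 0.95,
#'   inclusive).
#' @return A `similarity_table` restricted to the passing diseases.
#' @export
screen_diseases <- function(dga, focal, threshold = 0.95,
                            measure = c("overlap", "jaccard", "dice")) {
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            threshold >= 0, threshold <= 1)
  tab <- disease_similarity(dga, focal, measure)
  out <- tab[tab$similarity >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, focal = attr(tab, "focal"), measure = attr(tab, "measure"),
            threshold = threshold, class = class(tab))
}
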
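#' Tripartite disease-gene-drug association network
#'
#' Joins a drug-gene interaction (DGI) network and a disease-gene
#' association (DGA) network on their shared gene layer. Both edge sets are
#' stored unmodified; gene ids are compared in one canonical (string)
#' namespace.
#'
#' @param dgi a `bipartite_network`, drugs on side a, genes on side b.
#' @param dga a `bipartite_network`, diseases on side a, genes on side b.
#' @return An object of class `tripartite_network`: `dgi`, `dga`, `genes`
#'   (the union universe) and logical flags `in_dgi`, `in_dga` per gene.
#' @export
tripartite_network <- function(dgi, dga) {
  stopifnot(inherits(dgi, "bipartite_network"), inherits(dga, "bipartite_network"))
  genes <- sort(union(dgi$side_b, dga$side_b))
  structure(list(dgi = dgi, dga = dga, genes = genes,
                 in_dgi = genes %in% dgi$side_b,
                 in_dga = genes %in% dga$side_b),
            class = "tripartite_network")
}

#' @export
print.tripartite_network <- function(x, ...) {
  cat(sprintf(paste0("tripartite_network: %d drugs, %d diseases, %d genes ",
                     "(%d shared by both layers)\n"),
              length(x$dgi$side_a), length(x$dga$side_a), length(x$genes),
              sum(x$in_dgi & x$in_dga)))
  invisible(x)
}

#' Binary drug-disease connectivity matrix
#'
#' A drug and a disease are connected when at least one gene links them:
#' some gene g with (drug, g) in the DGI and (disease, g) in the DGA. The
#' matrix is the boolean (saturating) product of the restricted drug-gene
#' incidence matrix with the transposed restricted disease-gene incidence
#' matrix — multiple gene paths still give a 1.
#'
#' @param tri a [tripartite_network()].
#' @param drugs,diseases non-empty id subsets (default: all drugs /
#'   diseases in the respective layer). Typically the candidates from the
#'   enrichment screen and the diseases from the similarity screen.
#' @return A binary matrix, drugs as rows, diseases as columns.
#' @export
build_drug_disease_matrix <- function(tri, drugs = NULL, diseases = NULL) {
  stopifnot(inherits(tri, "tripartite_network"))
  if (is.null(drugs)) drugs <- tri$dgi$side_a
  if (is.null(diseases)) diseases <- tri$dga$side_a
  drugs <- sort(unique(as.character(drugs)))
  diseases <- sort(unique(as.character(diseases)))
  if (!length(drugs)) stop("build_drug_disease_matrix: empty drug subset")
  if (!length(diseases)) stop("build_drug_disease_matrix: empty disease subset")
  if (!all(drugs %in% tri$dgi$side_a))
    stop("unknown drug(s): ", paste(setdiff(drugs, tri$dgi$side_a), collapse = ", "))
  if (!all(diseases %in% tri$dga$side_a))
    stop("unknown disease(s): ",
         paste(setdiff(diseases, tri$dga$side_a), collapse = ", "))
  genes <- tri$genes
  ed_g <- tri$dgi$edges[tri$dgi$edges$a %in% drugs, , drop = FALSE]
  ed_z <- tri$dga$edges[tri$dga$edges$a %in% diseases, , drop = FALSE]
  a <- Matrix::sparseMatrix(i = match(ed_g$a, drugs), j = match(ed_g$b, genes),
                            x = 1, dims = c(length(drugs), length(genes)),
                            dimnames = list(drugs, genes))
  b <- Matrix::sparseMatrix(i = match(ed_z$a, diseases), j = match(ed_z$b, genes),
                            x = 1, dims = c(length(diseases), length(genes)),
                            dimnames = list(diseases, genes))
  m <- as.matrix(Matrix::tcrossprod(a, b))
  (m > 0) + 0L
}

#' Disease coverage score (DCS)
#'
#' Number of screened diseases a drug reaches through at least one gene
#' path: the drug's row sum in the binary drug-disease matrix.
#'
#' @param m a drug-disease matrix from [build_drug_disease_matrix()].
#' @param drug_id a single drug id, or `NULL` for all rows.
#' @return A named integer vector of row sums.
#' @export
dcs <- function(m, drug_id = NULL) {
  stopifnot(is.matrix(m))
  if (is.null(drug_id)) return(stats::setNames(as.integer(rowSums(m)), rownames(m)))
  if (!drug_id %in% rownames(m)) stop("unknown drug: ", drug_id)
  stats::setNames(as.integer(sum(m[drug_id, ])), drug_id)
}

#' Gene association score (GAS)
#'
#' Number of unique genes a drug interacts with: its degree in the
#' drug-gene interaction network.
#'
#' @param dgi a `bipartite_network`, drugs on side a.
#' @param drug_id a single drug id, or `NULL` for all drugs.
#' @return A named integer vector of DGI degrees.
#' @export
gas <- function(dgi, drug_id = NULL) {
  stopifnot(inherits(dgi, "bipartite_network"))
  deg <- table(factor(dgi$edges$a, levels = dgi$side_a))
  deg <- stats::setNames(as.integer(deg), dgi$side_a)
  if (is.null(drug_id)) return(deg)
  if (!drug_id %in% dgi$side_a) stop("unknown drug: ", drug_id)
  deg[drug_id]
}

#' Weighted total score
#'
#' `alpha * DCS + beta * GAS`; with the default unit weights the two raw
#' counts contribute equally, no rescaling applied.
#'
#' @param dcs,gas numeric vectors (recycled as usual).
#' @param alpha,beta weights, default 1.
#' @return `alpha * dcs + beta * gas`.
#' @examples
#' total_score(76, 5)  # 81
#' @export
total_score <- function(dcs, gas, alpha = 1, beta = 1) {
  stopifnot(is.numeric(dcs), is.numeric(gas),
            all(is.finite(alpha)), all(is.finite(beta)))
  alpha * dcs + beta * gas
}

#' Intersect two candidate drug sets
#'
#' @param set_a,set_b character vectors of drug ids.
#' @return Sorted intersection.
#' @export
intersect_candidates <- function(set_a, set_b) {
  sort(intersect(unique(as.character(set_a)), unique(as.character(set_b))))
}

#' Rank scored drugs
#'
#' Sorts by total score descending, breaking ties by DCS descending and
#' then lexicographic drug id, and assigns 1-based ranks on the total
#' score: competition ranking (ties share a rank and the next rank is
#' skipped: 1, 2, 2, 4) or dense ranking (1, 2, 2, 3).
#'
#' @param records data frame with columns `drug_id`, `dcs`, `gas`, `total`.
#' @param ties `"competition"` (default) or `"dense"`.
#' @return The records sorted, with a `rank` column added.
#' @export
rank_drugs <- function(records, ties = c("competition", "dense")) {
  ties <- match.arg(ties)
  stopifnot(is.data.frame(records),
            all(c("drug_id", "dcs", "gas", "total") %in% names(records)))
  out <- records[order(-records$total, -records$dcs, records$drug_id), ,
                 drop = FALSE]
  out$rank <- if (ties == "competition") {
    as.integer(rank(-out$total, ties.method = "min"))
  } else {
    as.integer(match(out$total, unique(out$total)))
  }
  rownames(out) <- NULL
  out
}

#' Score and rank candidate drugs through the tripartite network
#'
#' Convenience wrapper: builds the drug-disease matrix over the given drug
#' and disease subsets, computes DCS (path-connected screened diseases) and
#' GAS (DGI degree) per drug, the weighted total, and ranks.
#'
#' @param tri a [tripartite_network()].
#' @param drugs candidate drug ids.
#' @param diseases screened disease ids.
#' @param alpha,beta total-score weights.
#' @param ties ranking mode, see [rank_drugs()].
#' @return A ranked data frame: `drug_id`, `dcs`, `gas`, `total`, `rank`.
#' @export
score_drugs <- function(tri, drugs, diseases, alpha = 1, beta = 1,
                        ties = c("competition", "dense")) {
  m <- build_drug_disease_matrix(tri, drugs, diseases)
  d <- dcs(m)
  g <- gas(tri$dgi)[rownames(m)]
  rec <- data.frame(drug_id = rownames(m), dcs = unname(d), gas = unname(g),
                    total = unname(total_score(d, g, alpha, beta)),
                    stringsAsFactors = FALSE)
  rank_drugs(rec, match.arg(ties))
}
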
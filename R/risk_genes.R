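#' Risk-gene sets
#'
#' A `risk_gene_set` holds a deduplicated set of gene identifiers, an
#' optional numeric relevance score per gene (e.g. a database inference
#' score, dimensionless), and a free-text provenance label. Risk genes seed
#' both screening arms of the pipeline: cluster enrichment and
#' focal-disease similarity.
#'
#' @param genes character vector of gene ids.
#' @param scores optional numeric vector, one finite score per gene.
#' @param source_label free-text provenance.
#' @return An object of class `risk_gene_set`: sorted unique `genes`, a
#'   named `scores` vector (or `NULL`), and `source_label`.
#' @export
risk_gene_set <- function(genes, scores = NULL, source_label = "") {
  genes <- as.character(genes)
  if (anyNA(genes) || any(genes == "")) stop("gene ids must be non-empty strings")
  if (!is.null(scores)) {
    if (length(scores) != length(genes))
      stop("scores must align one-to-one with genes")
    if (!all(is.finite(scores))) stop("scores must be finite")
    keep <- !duplicated(genes)
    dup <- genes[!keep]
    if (length(dup) && any(scores[!keep] != scores[match(dup, genes)]))
      stop("conflicting scores for duplicated gene ids: ",
           paste(unique(dup), collapse = ", "))
    scores <- scores[keep]
    names(scores) <- genes[keep]
    scores <- scores[order(names(scores))]
    genes <- names(scores)
  } else {
    genes <- sort(unique(genes))
  }
  structure(list(genes = genes, scores = scores, source_label = source_label),
            class = "risk_gene_set")
}

#' @export
print.risk_gene_set <- function(x, ...) {
  cat(sprintf("risk_gene_set%s: %d genes%s\n",
              if (nzchar(x$source_label)) paste0(" [", x$source_label, "]") else "",
              length(x$genes),
              if (is.null(x$scores)) "" else " (scored)"))
  invisible(x)
}

#' Read a gene list from a plain-text file
#'
#' One gene per line; an optional second whitespace- or tab-separated column
#' is read as a numeric relevance score.
#'
#' @param path path to the file.
#' @param source_label provenance label; defaults to the file name.
#' @return A [risk_gene_set()].
#' @export
read_gene_list <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no genes found in ", path)
  fields <- strsplit(lines, "[\t ]+")
  genes <- vapply(fields, `[[`, "", 1L)
  nf <- vapply(fields, length, 1L)
  if (all(nf >= 2)) {
    scores <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
    bad <- which(is.na(scores))
    if (length(bad))
      stop(sprintf("non-numeric score at line %d of %s", bad[[1]], path))
    risk_gene_set(genes, scores, source_label)
  } else {
    risk_gene_set(genes, source_label = source_label)
  }
}

#' Keep the top-scoring fraction of a risk-gene set
#'
#' Selects the `ceiling(fraction * n)` highest-scoring genes. Ties at the
#' cut boundary are broken deterministically by lexicographic gene id, so
#' the selection is reproducible and nested: the result for a smaller
#' fraction is always a subset of the result for a larger one.
#'
#' @param x a scored `risk_gene_set`.
#' @param fraction fraction in (0, 1] to keep.
#' @return A `risk_gene_set` with the selected genes (scores retained).
#' @seealso [filter_top_n()] to pick an exact count instead.
#' @export
filter_top_fraction <- function(x, fraction) {
  stopifnot(inherits(x, "risk_gene_set"))
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      !is.finite(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be a single number in (0, 1]")
  filter_top_n(x, ceiling(fraction * length(x$genes)))
}

#' Keep the top-n highest-scoring genes of a risk-gene set
#'
#' Direct-count variant of [filter_top_fraction()] for when the desired
#' number of genes is known exactly rather than as a fraction.
#'
#' @param x a scored `risk_gene_set`.
#' @param n number of genes to keep (capped at the set size).
#' @return A `risk_gene_set` with the `n` top-scored genes.
#' @export
filter_top_n <- function(x, n) {
  stopifnot(inherits(x, "risk_gene_set"))
  if (is.null(x$scores)) stop("filter_top_n: gene set has no scores")
  if (!is.numeric(n) || length(n) != 1 || n < 1) stop("n must be a positive count")
  n <- min(as.integer(n), length(x$genes))
  ord <- order(-x$scores, names(x$scores))
  keep <- names(x$scores)[ord[seq_len(n)]]
  risk_gene_set(keep, unname(x$scores[keep]), x$source_label)
}

#' Merge several risk-gene sets by union
#'
#' Scores are dropped on merge (sources score on incompatible scales); the
#' provenance label concatenates the inputs' labels.
#'
#' @param sets a non-empty list of `risk_gene_set` objects.
#' @return A `risk_gene_set` holding the union of gene ids.
#' @export
merge_risk_sets <- function(sets) {
  if (!is.list(sets) || length(sets) == 0)
    stop("merge_risk_sets: need at least one set")
  if (!all(vapply(sets, inherits, TRUE, "risk_gene_set")))
    stop("merge_risk_sets: all elements must be risk_gene_set objects")
  genes <- sort(unique(unlist(lapply(sets, `[[`, "genes"))))
  labels <- vapply(sets, `[[`, "", "source_label")
  labels <- labels[nzchar(labels)]
  risk_gene_set(genes, source_label = paste(labels, collapse = " + "))
}
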
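#' Construct a bipartite network
#'
#' A `bipartite_network` stores two disjoint node universes (side "a", e.g.
#' drugs or diseases, and side "b", genes) together with a deduplicated edge
#' set between them. Identifiers are opaque, case-sensitive strings; no
#' symbol normalisation is performed.
#'
#' @param edges a two-column data frame (or matrix) of edges; first column is
#'   the side-a endpoint, second the side-b endpoint.
#' @param side_a,side_b optional character vectors of node ids. Defaults to
#'   the ids appearing in `edges`; ids given here but absent from `edges` are
#'   kept as isolated nodes.
#' @param name free-text label for the network.
#' @return An object of class `bipartite_network`: a list with sorted unique
#'   `side_a`, `side_b`, a sorted deduplicated `edges` data frame (columns
#'   `a`, `b`) and `name`.
#' @examples
#' net <- bipartite_network(data.frame(a = c("d1", "d1", "d2"),
#'                                     b = c("g1", "g2", "g1")))
#' n_edges(net)
#' @export
bipartite_network <- function(edges, side_a = NULL, side_b = NULL, name = "") {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(edges), ncol(edges) >= 2)
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  if (nrow(edges) > 0 && (anyNA(a) || anyNA(b) || any(a == "") || any(b == "")))
    stop("edge endpoints must be non-empty, non-missing identifiers")
  ed <- unique(data.frame(a = a, b = b, stringsAsFactors = FALSE))
  ed <- ed[order(ed$a, ed$b), , drop = FALSE]
  rownames(ed) <- NULL
  side_a <- sort(unique(c(as.character(side_a), ed$a)))
  side_b <- sort(unique(c(as.character(side_b), ed$b)))
  structure(list(side_a = side_a, side_b = side_b, edges = ed, name = name),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite_network%s: %d side-a nodes, %d side-b nodes, %d edges\n",
              if (nzchar(x$name)) paste0(" '", x$name, "'") else "",
              length(x$side_a), length(x$side_b), nrow(x$edges)))
  invisible(x)
}

#' @rdname bipartite_network
#' @param net a `bipartite_network`.
#' @export
n_edges <- function(net) nrow(net$edges)

## Sparse 0/1 incidence matrix, side-a rows x side-b columns.
incidence_matrix <- function(net) {
  Matrix::sparseMatrix(
    i = match(net$edges$a, net$side_a),
    j = match(net$edges$b, net$side_b),
    x = 1,
    dims = c(length(net$side_a), length(net$side_b)),
    dimnames = list(net$side_a, net$side_b))
}

#' Read a bipartite edge list from a delimited file
#'
#' Reads BioSNAP-style edge lists (e.g. ChG-Miner drug-gene TSVs, two
#' columns, or DG-AssocMiner disease-gene TSVs, where the gene sits in the
#' third column). Row order and duplicated rows do not affect the result.
#'
#' @param path path to the file.
#' @param columns integer pair: which fields hold the side-a and side-b ids
#'   (1-based). Default `c(1, 2)`; use `c(1, 3)` for disease files carrying a
#'   name column.
#' @param delimiter field separator, default tab.
#' @param header `"auto"` (default) treats a first line starting with `#` as
#'   a header, the BioSNAP convention; `TRUE`/`FALSE` force the choice.
#' @param name label stored on the network; defaults to the file name.
#' @return A [bipartite_network()].
#' @export
read_edge_list <- function(path, columns = c(1L, 2L), delimiter = "\t",
                           header = "auto", name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(length(columns) == 2, all(columns >= 1))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (identical(header, "auto")) header <- length(lines) > 0 && startsWith(lines[[1]], "#")
  first <- if (isTRUE(header)) 2L else 1L
  if (length(lines) < first) stop("no edges found in ", path)
  fields <- strsplit(lines[first:length(lines)], delimiter, fixed = TRUE)
  need <- max(columns)
  bad <- which(vapply(fields, length, 1L) < need)
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s: fewer than %d fields",
                 bad[[1]] + first - 1L, path, need))
  a <- vapply(fields, `[[`, "", columns[[1]])
  b <- vapply(fields, `[[`, "", columns[[2]])
  bipartite_network(data.frame(a = a, b = b, stringsAsFactors = FALSE),
                    name = name)
}

#' Write a bipartite network as a canonical (sorted) edge-list TSV
#'
#' @param net a `bipartite_network`.
#' @param path output path.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "bipartite_network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Degree summary of one side of a bipartite network
#'
#' Reports edge and node counts and the maximum, minimum and mean degree of
#' the chosen side. The mean is stored at full precision (`n_edges /
#' n_nodes` on that side); round for display.
#'
#' @param net a `bipartite_network` with at least one edge.
#' @param side `"a"` or `"b"`: which node universe to summarise.
#' @return A list of class `degree_summary`: `side`, `n_edges`, `n_side_a`,
#'   `n_side_b`, `max_degree`, `min_degree`, `mean_degree`,
#'   `n_nodes_at_min` (how many nodes sit at the minimum degree).
#' @export
degree_summary <- function(net, side = c("a", "b")) {
  stopifnot(inherits(net, "bipartite_network"))
  side <- match.arg(side)
  if (nrow(net$edges) == 0) stop("degree_summary: network has no edges")
  ids <- if (side == "a") net$side_a else net$side_b
  ends <- if (side == "a") net$edges$a else net$edges$b
  deg <- table(factor(ends, levels = ids))
  deg <- as.integer(deg)
  structure(list(side = side,
                 n_edges = nrow(net$edges),
                 n_side_a = length(net$side_a),
                 n_side_b = length(net$side_b),
                 max_degree = max(deg),
                 min_degree = min(deg),
                 mean_degree = nrow(net$edges) / length(ids),
                 n_nodes_at_min = sum(deg == min(deg))),
            class = "degree_summary")
}

#' @export
print.degree_summary <- function(x, ...) {
  cat(sprintf("degree summary (side %s): %d edges over %d nodes\n",
              x$side, x$n_edges, if (x$side == "a") x$n_side_a else x$n_side_b))
  cat(sprintf("  degree max %d, min %d (%d nodes at min), mean %.3f\n",
              x$max_degree, x$min_degree, x$n_nodes_at_min, x$mean_degree))
  invisible(x)
}

#' Write a degree summary as a JSON report
#'
#' @param x a `degree_summary`.
#' @param path output path.
#' @export
write_degree_summary <- function(x, path) {
  stopifnot(inherits(x, "degree_summary"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
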
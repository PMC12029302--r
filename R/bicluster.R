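#' Folding and clustering parameters
#'
#' `fold_params()` holds the thresholds that convert a bipartite graph to a
#' weighted simple graph: two same-side nodes are connected when their
#' neighbour sets share at least `relation_min` genes (the relation number)
#' AND have Tanimoto coefficient (|intersection| / |union|) at least
#' `tanimoto_min`. `cluster_params()` holds the density-clustering and
#' attachment thresholds. Defaults are the balanced settings for a sparse
#' drug-target network: Tanimoto 0.1, relation number 1, cluster density
#' 0.5, cluster property 0.5, attachment probability 0.5.
#'
#' @param tanimoto_min minimum Tanimoto coefficient, in \[0, 1\].
#' @param relation_min minimum shared-neighbour count (inclusive).
#' @return A validated parameter list.
#' @export
fold_params <- function(tanimoto_min = 0.1, relation_min = 1L) {
  stopifnot(is.numeric(tanimoto_min), tanimoto_min >= 0, tanimoto_min <= 1,
            is.numeric(relation_min), relation_min >= 0)
  structure(list(tanimoto_min = tanimoto_min,
                 relation_min = as.integer(relation_min)),
            class = "fold_params")
}

#' @rdname fold_params
#' @param cluster_property_min minimum cluster property (periphery control)
#'   a candidate node must reach to join a growing cluster.
#' @param density_min minimum edge density of every emitted cluster, in
#'   (0, 1\].
#' @param attachment_min minimum fraction of a cluster's primary nodes a
#'   second-set node must connect to for inclusion in the bi-cluster.
#' @export
cluster_params <- function(cluster_property_min = 0.5, density_min = 0.5,
                           attachment_min = 0.5) {
  stopifnot(is.numeric(density_min), density_min > 0, density_min <= 1,
            is.numeric(attachment_min), attachment_min >= 0, attachment_min <= 1,
            is.numeric(cluster_property_min), cluster_property_min >= 0)
  structure(list(cluster_property_min = cluster_property_min,
                 density_min = density_min,
                 attachment_min = attachment_min),
            class = "cluster_params")
}

#' Fold a bipartite network onto one side
#'
#' Projects the bipartite graph onto the chosen side's node set. For every
#' pair of same-side nodes u, v with neighbour sets N(u), N(v), the relation
#' number is |N(u) ∩ N(v)| and the Tanimoto coefficient is
#' |N(u) ∩ N(v)| / |N(u) ∪ N(v)|; an edge is stored iff both thresholds in
#' `params` are met. Computed via a sparse incidence cross-product, so large
#' sparse networks fold cheaply.
#'
#' @param net a `bipartite_network`.
#' @param fold_side `"a"` (default; e.g. drugs) or `"b"`.
#' @param params a [fold_params()].
#' @return An object of class `simple_graph`: `nodes` (all folded-side ids,
#'   sorted) and `edges`, a data frame with columns `u`, `v` (u < v),
#'   `tanimoto`, `relation`.
#' @export
fold <- function(net, fold_side = c("a", "b"), params = fold_params()) {
  stopifnot(inherits(net, "bipartite_network"), inherits(params, "fold_params"))
  fold_side <- match.arg(fold_side)
  if (nrow(net$edges) == 0) stop("fold: network has no edges")
  m <- incidence_matrix(net)
  if (fold_side == "b") m <- Matrix::t(m)
  if (nrow(m) < 2) stop("fold: folded side has fewer than 2 nodes")
  nodes <- rownames(m)
  co <- Matrix::tcrossprod(m)            # relation numbers, all pairs
  deg <- Matrix::rowSums(m)
  tri <- Matrix::summary(Matrix::triu(co, k = 1))
  rel <- tri$x
  tan <- rel / (deg[tri$i] + deg[tri$j] - rel)
  keep <- rel >= params$relation_min & tan >= params$tanimoto_min
  ed <- data.frame(u = nodes[tri$i][keep], v = nodes[tri$j][keep],
                   tanimoto = tan[keep], relation = as.integer(rel[keep]),
                   stringsAsFactors = FALSE)
  swap <- ed$u > ed$v
  if (any(swap)) ed[swap, c("u", "v")] <- ed[swap, c("v", "u")]
  ed <- ed[order(ed$u, ed$v), , drop = FALSE]
  rownames(ed) <- NULL
  structure(list(nodes = nodes, edges = ed), class = "simple_graph")
}

#' @export
print.simple_graph <- function(x, ...) {
  cat(sprintf("simple_graph: %d nodes, %d weighted edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

## adjacency as a named list of sorted neighbour vectors
sg_adjacency <- function(g) {
  adj <- stats::setNames(vector("list", length(g$nodes)), g$nodes)
  for (n in g$nodes) adj[[n]] <- character()
  if (nrow(g$edges)) {
    by_u <- split(g$edges$v, g$edges$u)
    by_v <- split(g$edges$u, g$edges$v)
    for (n in names(by_u)) adj[[n]] <- c(adj[[n]], by_u[[n]])
    for (n in names(by_v)) adj[[n]] <- c(adj[[n]], by_v[[n]])
    adj <- lapply(adj, sort)
  }
  adj
}

sg_weights <- function(g) {
  if (!nrow(g$edges)) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(g$edges$tanimoto, paste(g$edges$u, g$edges$v, sep = "\r"))
}

edge_key <- function(u, v) {
  ifelse(u < v, paste(u, v, sep = "\r"), paste(v, u, sep = "\r"))
}

#' Edge density of a node set in a simple graph
#'
#' `2 E / (n (n - 1))` over the induced subgraph; a single node has density
#' 0 by convention and a connected pair has density 1.
#'
#' @param g a `simple_graph`.
#' @param nodes character vector of member ids.
#' @return Density in \[0, 1\].
#' @export
graph_density <- function(g, nodes) {
  n <- length(nodes)
  if (n < 2) return(0)
  e <- sum(g$edges$u %in% nodes & g$edges$v %in% nodes)
  2 * e / (n * (n - 1))
}

#' Density-based heuristic clustering of a simple graph
#'
#' A deterministic polynomial-time cluster-growing heuristic in the DPClus
#' family. Repeatedly: seed a new cluster at the highest-degree not-yet-
#' clustered node (ties lexicographic); greedily expand by adding, among the
#' cluster's neighbours, the qualifying node with the most edges into the
#' cluster (ties: larger total Tanimoto weight into the cluster, then
#' lexicographic id). A candidate qualifies when the density after adding it
#' stays at or above `density_min` and its cluster property
#' |edges(v, C)| / (density(C) * |C|) reaches `cluster_property_min` (a
#' size-1 cluster has density 0, so any connected neighbour qualifies).
#' Expansion stops when no candidate qualifies. Members are then marked
#' clustered — they no longer seed — but remain eligible for absorption
#' into later clusters, so clusters may overlap.
#'
#' @param g a `simple_graph`.
#' @param params a [cluster_params()].
#' @param keep_singletons if `TRUE` (default), nodes without any simple-
#'   graph edge are emitted as singleton clusters; if `FALSE` they are
#'   dropped.
#' @return A list of clusters in deterministic seed order, each a list with
#'   sorted `members` and recomputed `density`.
#' @export
cluster_graph <- function(g, params = cluster_params(), keep_singletons = TRUE) {
  stopifnot(inherits(g, "simple_graph"), inherits(params, "cluster_params"))
  adj <- sg_adjacency(g)
  wt <- sg_weights(g)
  deg <- vapply(adj, length, 1L)
  nodes <- g$nodes
  clustered <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  clusters <- list()
  seen <- character()

  seed_order <- nodes[order(-deg, nodes)]
  for (seed in seed_order) {
    if (clustered[[seed]] || deg[[seed]] == 0) next
    members <- seed
    e_in <- 0L
    repeat {
      n_c <- length(members)
      dens <- if (n_c < 2) 0 else 2 * e_in / (n_c * (n_c - 1))
      cand <- setdiff(unique(unlist(adj[members], use.names = FALSE)), members)
      if (!length(cand)) break
      cand <- sort(cand)
      k <- vapply(cand, function(v) length(intersect(adj[[v]], members)), 1L)
      new_dens <- 2 * (e_in + k) / ((n_c + 1) * n_c)
      cp <- if (dens * n_c == 0) ifelse(k >= 1, Inf, 0) else k / (dens * n_c)
      ok <- new_dens >= params$density_min & cp >= params$cluster_property_min
      if (!any(ok)) break
      cand <- cand[ok]; k <- k[ok]
      w <- vapply(cand, function(v)
        sum(wt[edge_key(v, intersect(adj[[v]], members))]), 0)
      pick <- cand[order(-k, -w, cand)][[1]]
      e_in <- e_in + k[[match(pick, cand)]]
      members <- c(members, pick)
    }
    members <- sort(members)
    clustered[members] <- TRUE
    key <- paste(members, collapse = "\r")
    if (!key %in% seen) {
      seen <- c(seen, key)
      clusters[[length(clusters) + 1L]] <-
        list(members = members, density = graph_density(g, members))
    }
  }
  if (keep_singletons) {
    for (n in nodes[deg == 0])
      clusters[[length(clusters) + 1L]] <- list(members = n, density = 0)
  }
  clusters
}

#' Attach second-set nodes to a folded-side cluster
#'
#' A second-set node x joins the bi-cluster iff it is adjacent (in the
#' original bipartite network) to at least `attachment_min` of the
#' cluster's primary nodes: |N(x) ∩ cluster| / |cluster| ≥ attachment_min.
#'
#' @param net the original `bipartite_network`.
#' @param cluster character vector of primary-side member ids (non-empty).
#' @param params a [cluster_params()]; only `attachment_min` is used.
#' @param fold_side which side of `net` the cluster lives on.
#' @param density density metadata to copy onto the bi-cluster.
#' @param cluster_id integer id to stamp on the bi-cluster.
#' @return An object of class `bicluster`: `primary_nodes`,
#'   `attached_nodes`, `density`, `cluster_id`.
#' @export
attach_nodes <- function(net, cluster, params = cluster_params(),
                         fold_side = c("a", "b"), density = NA_real_,
                         cluster_id = NA_integer_) {
  stopifnot(inherits(net, "bipartite_network"), inherits(params, "cluster_params"))
  fold_side <- match.arg(fold_side)
  if (!length(cluster)) stop("attach_nodes: empty cluster")
  side_ids <- if (fold_side == "a") net$side_a else net$side_b
  if (!all(cluster %in% side_ids))
    stop("attach_nodes: cluster nodes must belong to the folded side")
  prim <- if (fold_side == "a") net$edges$a else net$edges$b
  sec <- if (fold_side == "a") net$edges$b else net$edges$a
  hits <- table(sec[prim %in% cluster])
  attached <- names(hits)[as.vector(hits) / length(cluster) >= params$attachment_min]
  structure(list(primary_nodes = sort(cluster),
                 attached_nodes = sort(attached),
                 density = density,
                 cluster_id = as.integer(cluster_id)),
            class = "bicluster")
}

#' @export
print.bicluster <- function(x, ...) {
  cat(sprintf("bicluster %s: %d primary + %d attached nodes, density %.3f\n",
              ifelse(is.na(x$cluster_id), "?", x$cluster_id),
              length(x$primary_nodes), length(x$attached_nodes), x$density))
  invisible(x)
}

#' Full bi-clustering pipeline: fold, cluster, attach
#'
#' Composition of [fold()], [cluster_graph()] and [attach_nodes()]:
#' projects the bipartite network onto `fold_side`, clusters the folded
#' simple graph by the density heuristic, and attaches second-set nodes to
#' each cluster. The whole pipeline is deterministic; bi-clusters are
#' numbered in the clustering's seed order.
#'
#' @inheritParams fold
#' @param cparams a [cluster_params()].
#' @param keep_singletons passed to [cluster_graph()].
#' @return A list of `bicluster` objects.
#' @export
bicluster_pipeline <- function(net, fold_side = c("a", "b"),
                               params = fold_params(),
                               cparams = cluster_params(),
                               keep_singletons = TRUE) {
  fold_side <- match.arg(fold_side)
  g <- fold(net, fold_side, params)
  cl <- cluster_graph(g, cparams, keep_singletons)
  out <- vector("list", length(cl))
  for (i in seq_along(cl))
    out[[i]] <- attach_nodes(net, cl[[i]]$members, cparams, fold_side,
                             density = cl[[i]]$density, cluster_id = i)
  out
}
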
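# Independent oracles and toy-instance generators used across the suite.

# Random sparse bipartite network over na x nb nodes; guarantees >= 1 edge.
random_bipartite <- function(na, nb, p, prefix = c("d", "g")) {
  pairs <- expand.grid(a = paste0(prefix[1], seq_len(na)),
                       b = paste0(prefix[2], seq_len(nb)),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  keep <- runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample.int(nrow(pairs), 1)] <- TRUE
  bipartite_network(pairs[keep, , drop = FALSE],
                    side_a = paste0(prefix[1], seq_len(na)),
                    side_b = paste0(prefix[2], seq_len(nb)))
}

# All-pairs set-intersection folding oracle: plain loops over neighbour
# sets, no matrix algebra shared with fold().
fold_oracle <- function(net, fold_side = "a", tanimoto_min = 0.1,
                        relation_min = 1) {
  ids <- if (fold_side == "a") net$side_a else net$side_b
  own <- if (fold_side == "a") net$edges$a else net$edges$b
  oth <- if (fold_side == "a") net$edges$b else net$edges$a
  nbr <- lapply(ids, function(i) unique(oth[own == i]))
  names(nbr) <- ids
  rows <- list()
  for (i in seq_along(ids)) for (j in seq_len(i - 1)) {
    u <- ids[j]; v <- ids[i]
    rel <- length(intersect(nbr[[u]], nbr[[v]]))
    if (rel == 0) next
    tan <- rel / length(union(nbr[[u]], nbr[[v]]))
    if (rel >= relation_min && tan >= tanimoto_min)
      rows[[length(rows) + 1]] <- data.frame(u = u, v = v, tanimoto = tan,
                                             relation = rel,
                                             stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(u = character(), v = character(), tanimoto = numeric(),
                      relation = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$u, out$v), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Path-existence oracle on the tripartite graph: breadth-first search from
# each drug through the gene layer, cell by cell.
path_oracle <- function(dgi, dga, drugs, diseases) {
  m <- matrix(0L, length(drugs), length(diseases),
              dimnames = list(drugs, diseases))
  for (d in drugs) {
    frontier <- unique(dgi$edges$b[dgi$edges$a == d])   # genes one hop away
    reached <- unique(dga$edges$a[dga$edges$b %in% frontier])
    m[d, intersect(reached, diseases)] <- 1L
  }
  m
}

# Exhaustive maximal >= dmin-dense connected subgraph enumeration on a tiny
# simple graph given as an edge data frame (u, v). Used to validate the
# clustering heuristic's recoveries on hand-sized instances.
dense_subgraphs_oracle <- function(edges, nodes, dmin) {
  has_edge <- function(a, b)
    any((edges$u == a & edges$v == b) | (edges$u == b & edges$v == a))
  dens <- function(s) {
    if (length(s) < 2) return(0)
    e <- 0
    for (i in seq_along(s)) for (j in seq_len(i - 1))
      if (has_edge(s[i], s[j])) e <- e + 1
    2 * e / (length(s) * (length(s) - 1))
  }
  subsets <- unlist(lapply(2:length(nodes), function(k)
    combn(nodes, k, simplify = FALSE)), recursive = FALSE)
  keep <- Filter(function(s) dens(s) >= dmin, subsets)
  is_maximal <- vapply(keep, function(s)
    !any(vapply(keep, function(t) length(t) > length(s) && all(s %in% t), TRUE)),
    TRUE)
  lapply(keep[is_maximal], sort)
}

jaccard_sets <- function(a, b) length(intersect(a, b)) / length(union(a, b))
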
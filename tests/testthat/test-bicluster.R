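test_that("fold computes relation number and Tanimoto coefficient exactly", {
  # N(u)={g1,g2}, N(v)={g2,g3}: relation 1, tanimoto 1/3, kept at defaults
  net <- bipartite_network(data.frame(a = c("u", "u", "v", "v"),
                                      b = c("g1", "g2", "g2", "g3")))
  g <- fold(net)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$relation, 1L)
  expect_equal(g$edges$tanimoto, 1 / 3)

  # identical neighbour sets of size k: tanimoto 1, relation k
  k <- 4
  net2 <- bipartite_network(data.frame(a = rep(c("u", "v"), each = k),
                                       b = rep(paste0("g", 1:k), 2)))
  g2 <- fold(net2)
  expect_equal(g2$edges$tanimoto, 1.0)
  expect_equal(g2$edges$relation, k)

  # one shared gene out of 19: tanimoto 1/19 < 0.1 -> edge dropped
  net3 <- bipartite_network(data.frame(
    a = c(rep("u", 10), rep("v", 10)),
    b = c(paste0("g", 1:10), paste0("g", 10:19))))
  expect_equal(nrow(fold(net3)$edges), 0)
  expect_equal(nrow(fold(net3, params = fold_params(tanimoto_min = 0))$edges), 1)
})

test_that("fold matches the all-pairs brute-force oracle on random graphs", {
  set.seed(101)
  for (i in 1:20) {
    net <- random_bipartite(sample(4:9, 1), sample(4:9, 1), runif(1, 0.15, 0.5))
    for (side in c("a", "b")) {
      if (length(if (side == "a") net$side_a else net$side_b) < 2) next
      got <- fold(net, side, fold_params(tanimoto_min = 0.1, relation_min = 1))
      want <- fold_oracle(net, side, 0.1, 1)
      expect_equal(got$edges, want)
    }
  }
})

test_that("cluster_graph recovers two 4-cliques joined by a bridge", {
  # exhaustive enumeration on this 8-node instance confirms the two
  # 4-cliques are the maximal >= 0.5-dense subgraphs containing them
  cliq <- function(nodes) t(combn(nodes, 2))
  left <- paste0("a", 1:4); right <- paste0("b", 1:4)
  ed <- rbind(cliq(left), cliq(right), c("a1", "b1"))
  # build through fold: give each simple-graph edge a shared gene
  bip <- bipartite_network(data.frame(
    a = c(ed[, 1], ed[, 2]),
    b = rep(sprintf("g%02d", seq_len(nrow(ed))), 2)))
  g <- fold(bip, params = fold_params(tanimoto_min = 0, relation_min = 1))
  expect_equal(nrow(g$edges), nrow(ed))
  cl <- cluster_graph(g, cluster_params(density_min = 0.5))
  members <- lapply(cl, `[[`, "members")
  expect_true(any(vapply(members, identical, TRUE, sort(left))))
  expect_true(any(vapply(members, identical, TRUE, sort(right))))
  # every emitted cluster sits inside some maximal >= 0.5-dense subgraph
  oracle <- dense_subgraphs_oracle(g$edges, g$nodes, 0.5)
  for (m in members)
    expect_true(any(vapply(oracle, function(o) all(m %in% o), TRUE)))
})

test_that("cluster_graph handles triangles, edgeless graphs and empty graphs", {
  tri <- structure(list(nodes = c("x", "y", "z"),
                        edges = data.frame(u = c("x", "x", "y"),
                                           v = c("y", "z", "z"),
                                           tanimoto = 1, relation = 1L,
                                           stringsAsFactors = FALSE)),
                   class = "simple_graph")
  cl <- cluster_graph(tri)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$members, c("x", "y", "z"))
  expect_equal(cl[[1]]$density, 1.0)

  bare <- structure(list(nodes = paste0("n", 1:5),
                         edges = data.frame(u = character(), v = character(),
                                            tanimoto = numeric(),
                                            relation = integer(),
                                            stringsAsFactors = FALSE)),
                    class = "simple_graph")
  expect_length(cluster_graph(bare), 5)            # five singletons
  expect_length(cluster_graph(bare, keep_singletons = FALSE), 0)

  empty <- structure(list(nodes = character(),
                          edges = bare$edges), class = "simple_graph")
  expect_length(cluster_graph(empty), 0)
})

test_that("every emitted cluster's recomputed density meets the floor", {
  set.seed(77)
  for (i in 1:10) {
    net <- random_bipartite(10, 12, runif(1, 0.1, 0.35))
    g <- fold(net, params = fold_params(tanimoto_min = 0.05))
    for (dmin in c(0.4, 0.6, 0.9)) {
      cl <- cluster_graph(g, cluster_params(density_min = dmin),
                          keep_singletons = FALSE)
      for (c_ in cl) {
        if (length(c_$members) == 1) next      # seeds with no qualifying mate
        expect_gte(graph_density(g, c_$members), dmin)
      }
    }
  }
})

test_that("attachment applies the coverage-ratio rule and is monotone", {
  net <- bipartite_network(data.frame(
    a = c("d1", "d2", "d1", "d2", "d3", "d4", "d1"),
    b = c("g1", "g1", "g2", "g2", "g2", "g2", "g3")))
  bc <- attach_nodes(net, c("d1", "d2"))
  # g1, g2 fully covered; g3 covers 1 of 2 = 0.5 -> attached at the
  # inclusive 0.5 default, dropped once the bar is raised
  expect_setequal(bc$attached_nodes, c("g1", "g2", "g3"))
  bc2 <- attach_nodes(net, c("d1", "d2"), cluster_params(attachment_min = 0.6))
  expect_setequal(bc2$attached_nodes, c("g1", "g2"))

  # over the 4-drug cluster: g1 hits 2/4 = 0.5 -> kept, g2 4/4 -> kept,
  # g3 hits 1/4 = 0.25 < 0.5 -> excluded
  bc4 <- attach_nodes(net, c("d1", "d2", "d3", "d4"))
  expect_setequal(bc4$attached_nodes, c("g1", "g2"))

  # raising attachment_min never adds nodes
  prev <- NULL
  for (am in c(0.25, 0.5, 0.75, 1)) {
    cur <- attach_nodes(net, c("d1", "d2", "d3", "d4"),
                        cluster_params(attachment_min = am))$attached_nodes
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  expect_error(attach_nodes(net, character()), "empty")
  expect_error(attach_nodes(net, "g1"), "folded side")
})

test_that("pipeline recovers disjoint planted blocks exactly and deterministically", {
  cfg <- synth_config(n_drugs = 40, n_genes = 80, n_planted_biclusters = 3,
                      planted_drug_size = 5, planted_gene_size = 5,
                      p_within = 1, p_background = 0, seed = 2)
  out <- generate_dgi(cfg)
  bcs <- bicluster_pipeline(out$network, keep_singletons = FALSE)
  big <- Filter(function(b) length(b$primary_nodes) >= 2, bcs)
  expect_length(big, 3)
  for (blk in out$truth$blocks) {
    match_j <- vapply(big, function(b)
      jaccard_sets(b$primary_nodes, blk$drugs), 0)
    best <- big[[which.max(match_j)]]
    expect_equal(best$primary_nodes, sort(blk$drugs))   # Jaccard 1.0
    expect_equal(best$attached_nodes, sort(blk$genes))  # complete 5x5: all attach
  }
  # no hidden randomness: identical output across runs
  expect_identical(bcs, bicluster_pipeline(out$network, keep_singletons = FALSE))
  expect_error(bicluster_pipeline(
    bipartite_network(data.frame(a = character(), b = character()))),
    "no edges")
})

test_that("attached gene membership in a bicluster follows from the bipartite edges", {
  # g1 attached to {d1,d2} (2/2); gene adjacent to 1 of 4 drugs excluded
  net <- bipartite_network(data.frame(a = c("d1", "d2"), b = c("g1", "g1")))
  expect_equal(attach_nodes(net, c("d1", "d2"))$attached_nodes, "g1")
})
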
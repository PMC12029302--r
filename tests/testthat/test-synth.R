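test_that("degenerate probabilities plant exact complete blocks", {
  cfg <- synth_config(n_drugs = 20, n_genes = 30, n_planted_biclusters = 1,
                      planted_drug_size = 5, planted_gene_size = 5,
                      p_within = 1, p_background = 0, seed = 3)
  out <- generate_dgi(cfg)
  expect_equal(n_edges(out$network), 25)   # one complete 5x5 block, nothing else
  blk <- out$truth$blocks[[1]]
  expect_setequal(unique(out$network$edges$a), blk$drugs)
  expect_setequal(unique(out$network$edges$b), blk$genes)
  # non-block nodes reported as isolated, not silently dropped
  expect_length(out$truth$isolated_drugs, 15)
})

test_that("seed changes background but never the planted blocks at p_within = 1", {
  mk <- function(seed) generate_dgi(synth_config(
    n_drugs = 30, n_genes = 40, n_planted_biclusters = 2,
    planted_drug_size = 4, planted_gene_size = 5,
    p_within = 1, p_background = 0.01, seed = seed))
  x <- mk(11); y <- mk(99)
  block_edges <- function(out) {
    keep <- rep(FALSE, n_edges(out$network))
    for (blk in out$truth$blocks)
      keep <- keep | (out$network$edges$a %in% blk$drugs &
                      out$network$edges$b %in% blk$genes)
    ed <- out$network$edges[keep, ]
    rownames(ed) <- NULL
    ed
  }
  expect_equal(block_edges(x), block_edges(y))          # planted part identical
  expect_false(identical(x$network$edges, y$network$edges))  # background differs
  # planted blocks are complete subgraphs of the generated network
  for (blk in x$truth$blocks) {
    want <- expand.grid(a = blk$drugs, b = blk$genes, stringsAsFactors = FALSE)
    have <- paste(x$network$edges$a, x$network$edges$b)
    expect_true(all(paste(want$a, want$b) %in% have))
  }
})

test_that("identical config and seed reproduce byte-identical files", {
  cfg <- synth_config(seed = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synth_dataset(cfg, d1)
  write_synth_dataset(cfg, d2)
  for (f in c("dgi.tsv", "dga.tsv", "risk_genes.txt", "truth.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("pure-background generation hits the target mean degree within 20%", {
  target_mean <- 3
  n_drugs <- 200; n_genes <- 400
  cfg <- synth_config(n_drugs = n_drugs, n_genes = n_genes,
                      n_planted_biclusters = 1, planted_drug_size = 1,
                      planted_gene_size = 1, p_within = 1,
                      p_background = target_mean / n_genes, seed = 21)
  out <- generate_dgi(cfg)
  realized <- n_edges(out$network) / n_drugs
  expect_lt(abs(realized - target_mean) / target_mean, 0.2)
})

test_that("risk-gene flags follow the per-block and background fractions", {
  cfg <- synth_config(n_drugs = 40, n_genes = 80, n_planted_biclusters = 3,
                      planted_drug_size = 4, planted_gene_size = 6,
                      risk_fraction_in_planted = c(1, 0.5, 0),
                      risk_fraction_background = 0, seed = 8)
  out <- generate_dgi(cfg)
  risk <- out$truth$risk_genes$genes
  blocks <- out$truth$blocks
  expect_length(intersect(risk, blocks[[1]]$genes), 6)
  expect_length(intersect(risk, blocks[[2]]$genes), 3)
  expect_length(intersect(risk, blocks[[3]]$genes), 0)
  expect_length(setdiff(risk, unlist(lapply(blocks, `[[`, "genes"))), 0)
})

test_that("generate_dga realises the requested overlap coefficients", {
  cfg <- synth_config(focal_gene_set_size = 20,
                      similarity_profile = c(1.0, 0.95, 0.0), seed = 13)
  out <- generate_dga(cfg)
  sets <- disease_gene_sets(out$network)
  focal <- out$truth$focal_genes
  expect_equal(sets[[out$truth$focal_disease_id]], focal)
  # s = 1: identical gene set; s = 0.95: ceiling(0.95*20) = 19 shared;
  # s = 0: disjoint — verified through the similarity module
  others <- setdiff(names(sets), out$truth$focal_disease_id)
  sims <- vapply(others, function(z)
    gene_set_similarity(sets[[z]], focal, "overlap"), 0)
  expect_equal(unname(sims), c(1.0, 19 / 20, 0.0))
  expect_equal(unname(out$truth$overlap[others]), c(1.0, 0.95, 0.0))
  expect_length(intersect(sets[[others[2]]], focal), 19)
})

test_that("an explicit focal gene set overrides the random draw", {
  cfg <- synth_config(n_genes = 100, similarity_profile = c(1.0, 0.5), seed = 6)
  focal <- c("G010", "G020", "G030", "G040")
  out <- generate_dga(cfg, focal_genes = focal)
  expect_equal(out$truth$focal_genes, focal)
  sets <- disease_gene_sets(out$network)
  expect_equal(sets[[out$truth$focal_disease_id]], focal)
  others <- setdiff(names(sets), out$truth$focal_disease_id)
  expect_equal(gene_set_similarity(sets[[others[1]]], focal, "overlap"), 1.0)
  expect_equal(gene_set_similarity(sets[[others[2]]], focal, "overlap"), 0.5)
  expect_error(generate_dga(cfg, focal_genes = c("G010", "NOPE")), "universe")
})

test_that("infeasible configurations are rejected up front", {
  expect_error(synth_config(p_within = 0.3, p_background = 0.5), "exceed")
  expect_error(synth_config(n_drugs = 5, n_planted_biclusters = 3,
                            planted_drug_size = 4), "fit")
  expect_error(synth_config(risk_fraction_in_planted = c(0.5, 0.5)),
               "per block")
  # overlap padding needs more fresh genes than exist outside the focal set
  cfg <- synth_config(n_genes = 25, focal_gene_set_size = 20,
                      similarity_profile = c(0.0))
  expect_error(generate_dga(cfg), "infeasible overlap")
})
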
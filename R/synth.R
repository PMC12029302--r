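#' Configuration for the synthetic network generator
#'
#' Defines a drug-gene interaction (DGI) network with planted dense
#' bi-clusters, a risk-gene labelling concentrated in chosen blocks, and a
#' disease-gene association (DGA) network with one focal disease plus other
#' diseases at controlled overlap-coefficient similarity to it. Defaults
#' give a sparse bipartite graph with three disjoint complete planted
#' blocks over a low-probability background — a scaled-down analogue of a
#' real drug-target network, with full ground truth.
#'
#' @param n_drugs,n_genes sizes of the two DGI node universes.
#' @param n_planted_biclusters number of planted drug-gene blocks.
#' @param planted_drug_size,planted_gene_size block dimensions; consecutive
#'   disjoint blocks are carved from the start of each universe.
#' @param p_within edge probability inside a planted block (must exceed
#'   `p_background`); 1 plants complete blocks.
#' @param p_background edge probability for every drug-gene pair outside
#'   the planted blocks.
#' @param risk_fraction_in_planted fraction of each planted block's genes
#'   flagged as risk genes; scalar or one value per block.
#' @param risk_fraction_background fraction of non-planted genes flagged.
#' @param focal_gene_set_size size of the focal disease's gene set.
#' @param similarity_profile target overlap coefficients, one per non-focal
#'   disease; disease i shares `ceiling(s_i * focal size)` genes with the
#'   focal set and is padded with non-focal genes to the focal size, so its
#'   realised overlap coefficient is `ceiling(s_i * f) / f`.
#' @param seed integer seed; fixed offsets derive per-stage substreams so
#'   e.g. adding diseases never perturbs the DGI draw.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_drugs = 60, n_genes = 120,
                         n_planted_biclusters = 3,
                         planted_drug_size = 6, planted_gene_size = 8,
                         p_within = 1.0, p_background = 0.005,
                         risk_fraction_in_planted = 1.0,
                         risk_fraction_background = 0.02,
                         focal_gene_set_size = 20,
                         similarity_profile = c(1.0, 0.95, 0.90, 0.50),
                         seed = 1L) {
  cfg <- list(n_drugs = as.integer(n_drugs), n_genes = as.integer(n_genes),
              n_planted_biclusters = as.integer(n_planted_biclusters),
              planted_drug_size = as.integer(planted_drug_size),
              planted_gene_size = as.integer(planted_gene_size),
              p_within = p_within, p_background = p_background,
              risk_fraction_in_planted = risk_fraction_in_planted,
              risk_fraction_background = risk_fraction_background,
              focal_gene_set_size = as.integer(focal_gene_set_size),
              similarity_profile = similarity_profile,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_drugs > 0, n_genes > 0, n_planted_biclusters >= 0,
              planted_drug_size > 0, planted_gene_size > 0,
              p_within > 0, p_within <= 1, p_background >= 0, p_background < 1)
    if (p_within <= p_background)
      stop("p_within must exceed p_background")
    if (n_planted_biclusters * planted_drug_size > n_drugs ||
        n_planted_biclusters * planted_gene_size > n_genes)
      stop("planted blocks do not fit inside the node universes")
    if (!length(risk_fraction_in_planted) %in% c(1L, max(1L, n_planted_biclusters)))
      stop("risk_fraction_in_planted must be scalar or one value per block")
    stopifnot(all(risk_fraction_in_planted >= 0), all(risk_fraction_in_planted <= 1),
              risk_fraction_background >= 0, risk_fraction_background <= 1,
              focal_gene_set_size > 0, focal_gene_set_size <= n_genes,
              all(similarity_profile >= 0), all(similarity_profile <= 1))
    if (abs(seed) > 2^31 - 2000) stop("seed out of range")
  })
  structure(cfg, class = "synth_config")
}

synth_ids <- function(prefix, n) {
  sprintf(paste0(prefix, "%0", max(2L, nchar(as.character(n))), "d"), seq_len(n))
}

planted_blocks <- function(cfg) {
  drugs <- synth_ids("D", cfg$n_drugs)
  genes <- synth_ids("G", cfg$n_genes)
  lapply(seq_len(cfg$n_planted_biclusters), function(i) {
    list(drugs = drugs[((i - 1) * cfg$planted_drug_size + 1):(i * cfg$planted_drug_size)],
         genes = genes[((i - 1) * cfg$planted_gene_size + 1):(i * cfg$planted_gene_size)])
  })
}

#' Generate a synthetic drug-gene interaction network with planted blocks
#'
#' Draws within-block edges with probability `p_within` and all remaining
#' drug-gene pairs with probability `p_background`. Fully reproducible:
#' identical config and seed give byte-identical edge lists.
#'
#' @param cfg a [synth_config()].
#' @return A list with `network` (a [bipartite_network()]) and `truth`, a
#'   list holding `blocks` (planted drug/gene memberships), `risk_genes`
#'   (a [risk_gene_set()]), and `isolated_drugs` / `isolated_genes`
#'   (nodes left without any edge, reported rather than dropped).
#' @export
generate_dgi <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  drugs <- synth_ids("D", cfg$n_drugs)
  genes <- synth_ids("G", cfg$n_genes)
  blocks <- planted_blocks(cfg)

  in_block <- matrix(FALSE, cfg$n_drugs, cfg$n_genes)
  set.seed(cfg$seed)                     # substream: planted edges
  edges <- list()
  for (blk in blocks) {
    di <- match(blk$drugs, drugs); gi <- match(blk$genes, genes)
    in_block[di, gi] <- TRUE
    pairs <- expand.grid(a = blk$drugs, b = blk$genes,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    keep <- stats::runif(nrow(pairs)) < cfg$p_within
    edges[[length(edges) + 1L]] <- pairs[keep, , drop = FALSE]
  }

  set.seed(cfg$seed + 1L)                # substream: background edges
  bg <- which(!in_block & matrix(stats::runif(cfg$n_drugs * cfg$n_genes),
                                 cfg$n_drugs, cfg$n_genes) < cfg$p_background,
              arr.ind = TRUE)
  if (nrow(bg))
    edges[[length(edges) + 1L]] <- data.frame(a = drugs[bg[, 1]],
                                              b = genes[bg[, 2]],
                                              stringsAsFactors = FALSE)
  ed <- do.call(rbind, c(edges, list(data.frame(a = character(), b = character(),
                                                stringsAsFactors = FALSE))))
  net <- bipartite_network(ed, side_a = drugs, side_b = genes,
                           name = "synthetic DGI")

  set.seed(cfg$seed + 2L)                # substream: risk-gene flags
  rf <- rep_len(cfg$risk_fraction_in_planted, max(1L, cfg$n_planted_biclusters))
  risk <- character()
  for (i in seq_along(blocks)) {
    k <- ceiling(rf[i] * length(blocks[[i]]$genes))
    if (k > 0) risk <- c(risk, sort(sample(blocks[[i]]$genes, k)))
  }
  non_planted <- setdiff(genes, unlist(lapply(blocks, `[[`, "genes")))
  k_bg <- round(cfg$risk_fraction_background * length(non_planted))
  if (k_bg > 0) risk <- c(risk, sort(sample(non_planted, k_bg)))

  truth <- list(
    blocks = blocks,
    risk_genes = risk_gene_set(risk, source_label = "synthetic risk genes"),
    isolated_drugs = setdiff(drugs, unique(net$edges$a)),
    isolated_genes = setdiff(genes, unique(net$edges$b)))
  list(network = net, truth = truth)
}

#' Generate a synthetic disease-gene association network
#'
#' Builds one focal disease with a gene set drawn from the DGI gene
#' universe, plus one disease per entry of `similarity_profile` constructed
#' to hit that overlap coefficient with the focal set: it copies
#' `ceiling(s * f)` focal genes and pads with fresh non-focal genes up to
#' the focal size `f`, so both sets have size `f` and the realised overlap
#' coefficient is exactly `ceiling(s * f) / f`.
#'
#' @param cfg a [synth_config()].
#' @param focal_genes optional explicit focal gene set (ids from the shared
#'   gene universe), overriding the random draw of `focal_gene_set_size`
#'   genes. Supplying the DGI truth's risk genes here couples the two
#'   evidence channels the way a real focal disease couples them: the
#'   diseases similar to the focal one then share the genes the risk-
#'   enriched bi-clusters act on.
#' @return A list with `network` (a [bipartite_network()], diseases on side
#'   a) and `truth`: `focal_disease_id`, `focal_genes`, and `overlap`, the
#'   realised per-disease overlap coefficient with the focal set.
#' @export
generate_dga <- function(cfg, focal_genes = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  genes <- synth_ids("G", cfg$n_genes)
  n_dis <- length(cfg$similarity_profile) + 1L
  diseases <- synth_ids("Z", n_dis)

  set.seed(cfg$seed + 1000L)             # substream: DGA, independent of DGI
  if (is.null(focal_genes)) {
    f <- cfg$focal_gene_set_size
    focal <- sort(sample(genes, f))
  } else {
    focal <- sort(unique(as.character(focal_genes)))
    if (!all(focal %in% genes))
      stop("focal_genes must lie in the generated gene universe")
    f <- length(focal)
  }
  non_focal <- setdiff(genes, focal)

  edges <- list(data.frame(a = diseases[[1]], b = focal, stringsAsFactors = FALSE))
  overlap <- numeric(0)
  for (i in seq_along(cfg$similarity_profile)) {
    s <- cfg$similarity_profile[[i]]
    k <- as.integer(ceiling(s * f))
    if (f - k > length(non_focal))
      stop("infeasible overlap: padding disease ", i, " needs ", f - k,
           " fresh genes but only ", length(non_focal), " exist outside the focal set")
    set.seed(cfg$seed + 1000L + i)       # substream per disease
    shared <- if (k > 0) sort(sample(focal, k)) else character()
    pad <- if (f - k > 0) sort(sample(non_focal, f - k)) else character()
    edges[[i + 1L]] <- data.frame(a = diseases[[i + 1L]], b = c(shared, pad),
                                  stringsAsFactors = FALSE)
    overlap[diseases[[i + 1L]]] <- k / f
  }
  net <- bipartite_network(do.call(rbind, edges), side_a = diseases,
                           side_b = genes, name = "synthetic DGA")
  truth <- list(focal_disease_id = diseases[[1]], focal_genes = focal,
                overlap = overlap)
  list(network = net, truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' Writes `dgi.tsv`, `dga.tsv`, `risk_genes.txt` and `truth.json` so the
#' whole pipeline can be exercised from files.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the list of file paths written.
#' @export
write_synth_dataset <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dgi <- generate_dgi(cfg)
  dga <- generate_dga(cfg)
  paths <- file.path(dir, c("dgi.tsv", "dga.tsv", "risk_genes.txt", "truth.json"))
  write_edge_list(dgi$network, paths[[1]])
  write_edge_list(dga$network, paths[[2]])
  writeLines(dgi$truth$risk_genes$genes, paths[[3]])
  jsonlite::write_json(
    list(blocks = lapply(dgi$truth$blocks, lapply, as.list),
         risk_genes = dgi$truth$risk_genes$genes,
         focal_disease_id = dga$truth$focal_disease_id,
         focal_genes = dga$truth$focal_genes,
         overlap = as.list(dga$truth$overlap)),
    paths[[4]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
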
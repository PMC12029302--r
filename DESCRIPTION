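Package: repnet
Title: Network-Based Drug Repurposing via Bipartite Bi-Clustering and
    Disease Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for network-based drug repurposing around a focal
    disease. Bi-clusters a drug-gene bipartite interaction network by
    folding it onto the drug side (Tanimoto coefficient and relation
    number), clustering the folded simple graph with a deterministic
    density-based heuristic in the DPClus family, and attaching genes to
    form overlapping bi-clusters. Bi-clusters are screened by a risk-gene
    enrichment fold; diseases are screened by gene-set similarity to the
    focal disease; the two evidence channels are joined through a
    tripartite drug-gene-disease network whose boolean matrix product
    yields disease coverage scores (DCS). Candidate drugs are ranked by a
    weighted sum of DCS and gene association score (GAS). Includes
    readers for BioSNAP-style edge lists, summary statistics, and a
    synthetic-data generator with planted bi-clusters and controlled
    disease similarity for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
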
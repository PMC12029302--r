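#!/usr/bin/env Rscript

# Optional integration run on the original database extracts, for
# qualitative comparison of stage counts only. The inputs are not shipped
# with the package; supply them as:
#
#   Rscript scripts/integration_real_data.R \
#     --dgi ChG-Miner_miner-chem-gene.tsv \
#     --dga DG-AssocMiner_miner-disease-gene.tsv \
#     --risk risk_genes.txt \
#     --out provenance.json
#
# --dgi: drug TAB gene edge list; --dga: disease id, disease name, gene
# (gene in column 3); --risk: one risk gene per line, optional score column.
# The full-scale funnel counts depend on heuristic internals that published
# descriptions underdetermine, so treat the output as order-of-magnitude.

suppressPackageStartupMessages(library(repnet))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[[i + 1]] else default
}
dgi_path <- get_arg("--dgi"); dga_path <- get_arg("--dga")
risk_path <- get_arg("--risk")
out_path <- get_arg("--out", "provenance.json")
if (is.null(dgi_path) || is.null(dga_path) || is.null(risk_path))
  stop("usage: --dgi <tsv> --dga <tsv> --risk <txt> [--out <json>]")

dgi <- read_edge_list(dgi_path)
dga <- read_edge_list(dga_path, columns = c(1, 3))
risk <- read_gene_list(risk_path)

print(degree_summary(dgi, "a"))
print(degree_summary(dga, "a"))

res <- run_pipeline(dgi, dga, risk)
print(res)
write_provenance(res, out_path)
cat("wrote", out_path, "\n")
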
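---
title: "Network-based drug repurposing: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based drug repurposing: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repnet)
```

## The problem

Drug repurposing asks which approved or investigational drugs might act on
a disease they were not developed for. `repnet` implements a two-channel
network strategy for a focal disease (the motivating use case is
non-alcoholic fatty liver disease, NAFLD, but nothing is NAFLD-specific):

1. **Bi-clustering channel.** A drug–gene interaction (DGI) network is
   bi-clustered into dense drug/gene modules; modules unusually rich in
   the focal disease's risk genes nominate their drugs.
2. **Disease-similarity channel.** Diseases whose gene sets closely
   resemble the focal disease's gene set are selected from a disease–gene
   association (DGA) network, and every drug that reaches one of them
   through a gene path in the joined tripartite (drug–gene–disease)
   network is nominated.

Drugs supported by *both* channels are ranked by a weighted sum of two
counts: the disease coverage score (DCS, how many of the screened
similar diseases a drug connects to through at least one gene) and the
gene association score (GAS, how many genes the drug interacts with at
all). With unit weights the total is simply `DCS + GAS`.

## The bi-clustering procedure

The bipartite DGI graph is first **folded** onto the drug side: two drugs
become adjacent in a simple graph when their target-gene sets share at
least `relation_min` genes (the *relation number*) and have Tanimoto
coefficient |A∩B|/|A∪B| of at least `tanimoto_min`. Folding is computed
as a sparse incidence cross-product, so all-pairs neighbour intersections
never materialise densely.

The folded graph is clustered with a deterministic density-based
heuristic in the DPClus family. Published descriptions of this algorithm
family fix the overall scheme (seeded greedy growth under a density floor
with a periphery-control "cluster property") but not every internal rule,
so this package defines and documents one deterministic variant:

* **Seeding.** The next cluster starts at the highest-degree node not yet
  in any cluster; ties break lexicographically.
* **Growth.** Among neighbours of the current cluster, the candidate with
  the most edges into the cluster is added (ties: larger summed Tanimoto
  weight into the cluster, then lexicographic id), provided the density
  after adding it stays at or above `density_min` *and* its cluster
  property |edges(v,C)| / (density(C)·|C|) reaches
  `cluster_property_min`. Density is 2E/(n(n−1)); a singleton has density
  0 by convention, which makes the cluster property formally infinite —
  any connected neighbour therefore qualifies to join a fresh seed, the
  only sensible degenerate reading.
* **Termination and overlap.** Growth stops when no candidate qualifies.
  Members then stop seeding new clusters but may be absorbed into later
  ones, so clusters can overlap, as overlapping bi-cluster schemes
  intend. Exact duplicates are emitted once. Isolated nodes become
  singletons (or are dropped via `keep_singletons = FALSE`).

Because seeding, growth and tie-breaking are all deterministic, two runs
on the same input are identical — a property the test suite asserts. The
variant is *a* faithful member of the family, not a bit-exact clone of
any particular released implementation; cluster counts on a given
dataset may differ from other implementations even at identical
parameters, which is why full-scale published cluster counts are treated
as order-of-magnitude context rather than reproduction targets.

Each simple-graph cluster is then **unfolded**: gene g joins the
bi-cluster when it touches at least `attachment_min` of the cluster's
drugs (inclusive comparison).

Default parameters (balanced settings for a sparse drug-target network,
all dimensionless): `tanimoto_min = 0.1`, `relation_min = 1`,
`density_min = 0.5`, `cluster_property_min = 0.5`,
`attachment_min = 0.5`.

## Enrichment screening

A bi-cluster with M attached genes, L of them risk genes, is scored
against a population of N genes containing K risk genes by the
enrichment fold (L/M)/(K/N). The population is the DGI gene universe —
the only universe under which cluster genes are a selected subset — and
K counts risk genes inside it. The default cut-off is 2.75, *inclusive*:
the reference analysis describes a cluster whose fold equals the
threshold exactly as selected, while its prose says "greater than"; both
readings are supported (`inclusive = FALSE`), the inclusive one is the
default so the worked-example narrative holds. Candidate drugs are the
union of primary nodes over passing clusters. No p-value machinery is
attached: the fold is the method's statistic.

## Disease similarity

Disease–disease similarity is computed from explicit gene-set overlap:
the overlap coefficient |A∩B|/min(|A|,|B|) by default, with Jaccard and
Dice as alternatives (always jaccard ≤ dice ≤ overlap). Ontology-based
semantic similarity, which the original analysis obtained from an
annotation-driven tool, is deliberately out of scope: it depends on
external ontology releases and configuration that cannot be pinned from
data alone, whereas set overlap is self-contained and testable. The
screening interface — keep diseases scoring at least a threshold in
[0,1], default 0.95 inclusive — is identical either way, but a threshold
calibrated for one measure transfers only qualitatively to another. The
focal disease may be a node of the DGA or an external gene list (e.g. a
curated risk-gene set), since the focal disease need not appear in the
association data.

## Tripartite scoring

DGI and DGA are joined on the gene layer. The drug–disease relation is
the boolean product of the restricted drug–gene incidence matrix with
the transposed restricted disease–gene matrix: entry 1 iff at least one
gene path links the pair; multiple paths do not add weight. DCS is a row
sum over the *screened* disease subset (so it depends on the similarity
threshold), GAS is the drug's DGI degree, and ranking sorts by
`α·DCS + β·GAS` (defaults α = β = 1, exposed but not normalised — the
two raw counts are added deliberately). Ties sort by DCS descending,
then id; rank numbers use competition ranking (1, 2, 2, 4) with a dense
option.

## The synthetic-data generator

`generate_dgi()` plants `n_planted_biclusters` disjoint drug×gene blocks
(edge probability `p_within`, default 1) over a Bernoulli background
(`p_background`, default 0.005 — about the edge density of a sparse
real drug-target network at this scale), flags risk genes by stratum
(per-block fractions and a background fraction), and reports isolated
nodes rather than dropping them. `generate_dga()` builds one focal
disease plus one disease per entry of `similarity_profile`, each sharing
`ceiling(s·f)` of the focal disease's f genes and padded with fresh
genes to size f, so the realised overlap coefficient is exactly
`ceiling(s·f)/f`. The focal set is drawn at random by default or
supplied explicitly (`focal_genes`); passing the planted risk genes
couples the two channels the way a real focal disease does. A single
integer seed drives fixed per-stage substreams (planted edges,
background, risk flags, each disease), so runs are byte-reproducible
and enlarging one stage never perturbs another.

What the generator emulates: sparsity, planted dense modules, risk
concentration, controlled focal similarity. What it does not: the heavy
degree tail of real interaction databases (no power-law fitting),
correlated noise, or identifier messiness. Passing the planted-recovery
tests therefore demonstrates correctness of the machinery, not
performance on real data.

## Numerical and degenerate-input choices

* Identifiers are opaque case-sensitive strings; matching is exact
  string equality after whitespace trimming at read time.
* Top-fraction risk filtering keeps `ceiling(fraction·n)` genes with a
  lexicographic tie-break at the boundary, giving deterministic, nested
  selections; `filter_top_n()` takes an exact count for when a published
  selection is "around" a percentage.
* Degree means are stored at full precision; display rounds to 3
  decimals.
* Folding thresholds are inclusive (≥); a fold side with fewer than two
  nodes, an empty edge set, an empty cluster, or an empty population are
  errors, not silent empties.
* Clusters of size 1 have density 0; a connected pair has density 1.

## Problem sizes

The test suite and the acceptance script run on synthetic networks of
roughly 50–200 drugs, 100–400 genes and a handful of diseases, with
50-instance randomized oracle comparisons; these sizes are where the
exhaustive and brute-force oracles (all-pairs folding, BFS
path-existence, maximal dense-subgraph enumeration) stay exact and fast
while still exercising every code path. The implementation itself is
sparse-matrix backed and handles database-scale inputs (thousands of
drugs) in seconds for folding and scoring; the clustering heuristic is
polynomial and dominated by the folded graph's edge count.

## Known limitations

* The clustering variant is deterministic and documented but not
  guaranteed to reproduce counts from other implementations of the same
  family on real data.
* Set-overlap similarity is not semantic similarity; thresholds
  calibrated on one do not transfer numerically to the other.
* The enrichment fold has no attached significance model; with very
  small clusters a high fold can rest on one or two genes.
* Gene identifiers are not normalised across databases; callers must
  reconcile namespaces before joining DGI and DGA layers.
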
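---
title: "Predicting giant-virus hosts from co-occurrence networks: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting giant-virus hosts from co-occurrence networks: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vhocnet)
```

## The problem

Nucleocytoplasmic large DNA viruses (NCLDVs, phylum *Nucleocytoviricota*)
are abundant in the oceans, but only a handful have been isolated with a
known host. Because a virus and its host wax and wane together, their
abundance profiles across many samples should co-vary, so a co-occurrence
network built from paired marker-gene tables — *polB* (family-B DNA
polymerase) OTUs for the viruses, 18S V9 metabarcode OTUs for the
eukaryotes — is a host-prediction machine: each polB–V9 edge is a
candidate virus–host pair. The catch is that such networks are awash in
edges driven by shared environmental preference, indirect ecological
links, and plain multiple-testing noise. This package implements the full
machinery for building those networks, quantifying how much better than
random their host predictions are, and filtering them with a viral
phylogeny.

## Preprocessing

Marker tables arrive as counts or as length-normalized relative
abundances. `relabund_to_counts()` undoes the length normalization
(`round(rel * gene_length / read_length * scale)`, read length 100 nt by
default) because downstream inference wants count-like magnitudes and
because relative abundances carry spurious negative correlations.
`clr_transform()` then applies the centered log-ratio per sample after
adding a pseudocount of 1: `clr_i = ln(x_i + 1) − mean_k ln(x_k + 1)`.
The clr is the standard guard against compositional artifacts; each
sample column sums to zero and the transform is invariant to per-sample
scaling. The composition is taken per sample across the OTUs of one
marker matrix — the point is to correct within-sample closure, not
per-OTU trends.

`quartile_filter()` removes low-abundance OTUs: the threshold is the
lower quartile (configurable to median or upper quartile) of the clr
values at cells that were non-zero in the original count matrix, and an
OTU is kept if it exceeds the threshold in at least 5 samples. Two
readings of "quartile among the non-zero counts" are possible — a single
global threshold, or one per OTU; the global reading is the default
(`scope = "per_otu"` gives the other) because the filter is meant to be a
single abundance bar for the whole matrix. Quantiles use R's default
linear interpolation between order statistics; this matters at quartile
boundaries and is therefore fixed and documented rather than left to
chance. Filtering is applied separately per marker, the full-matrix clr
values are kept for the retained OTUs (recomputation after filtering is
available via `recompute_clr = TRUE`), and `intersect_and_merge()` then
restricts both tables to their shared samples, prefixing OTU ids with the
marker so the id spaces cannot collide.

## Network inference

`spearman_network()` is the in-package comparator: Spearman's rho per
candidate polB–V9 pair (Pearson correlation of average ranks, ranks taken
per OTU across samples), an edge kept when its two-sided p-value passes
`alpha = 0.01`, the weight being rho itself (so weights live in [−1, 1]
and the sign splits the network into putative positive and negative
association classes). p-values use the t-approximation with n − 2 degrees
of freedom; an exact permutation p-value is available for n ≤ 10, where
the approximation is weakest. Raw significance is thresholded without
multiple-testing correction by default — the convention for these
networks, which are assessed downstream rather than interpreted
edge-by-edge; a BH option exists. Sparser, compositionally robust
networks from external tools (e.g. conditional-independence learners) can
be dropped in through `read_edges()`; everything downstream is agnostic
to the inference engine.

Environmental conditioning (`metavar_condition()`) approximates
indirect-edge removal: an edge survives only if, for every meta-variable
(temperature, salinity, nitrate, phosphate, silicate in the study design),
the first-order partial Spearman correlation given that variable stays
significant. Partial Spearman is computed as the Pearson partial
correlation of average ranks — a standard construction, and an
approximation of full conditional-independence testing that handles the
dominant single-confounder case well.

## Validation: LR+ and FDR

Known NCLDV–host pairs are too few for ROC analysis, so prediction
quality is measured with the positive likelihood ratio,

> LR+ = sensitivity / (1 − specificity),

over a candidate universe built as follows. Environmental polB OTUs are
grouped to reference viruses by their best homology hit
(`assign_reference_groups()`; best bitscore, ties by identity then
subject id) provided the hit reaches 65% identity — the level at which
reference NCLDVs sharing that much polB identity infect hosts of the same
"major lineage" (the intermediate rank of the PR2 V9 reference). A pair
(OTU, lineage) is condition positive when the OTU's reference virus has a
known host in that lineage. On the prediction side,
`reduce_best_edges()` keeps, per (OTU, lineage, sign), only the edge with
the largest absolute weight; pooled multi-fraction networks are thereby
also deduplicated. `confusion_matrix()` partitions the universe —
reference-assigned OTUs × a lineage vocabulary — into TP/FP/FN/TN, and
`lr_plus()` / `fdr()` derive the two headline statistics. LR+ = 1 means
the predictor is no better than random; `Inf` is returned when the
false-positive rate is zero with non-zero sensitivity, and `NA` (with a
warning) when the ratio is undefined.

Two deliberately configurable choices: the TN universe is all major
lineages supplied at run time (the most inclusive reading; the
alternative — lineages present in the network — just shrinks TN), and
positive and negative edge classes are assessed separately because they
plausibly reflect different infection dynamics. `sweep_cutoffs()`
re-assesses the matrix along an ascending weight-cutoff grid;
`random_predictor_lr()` provides the baseline by redrawing each OTU's
predicted lineages uniformly (its mean LR+ is ~1 by construction, which
the test suite verifies). When an LR+ average over a sweep is reported,
it is the unweighted mean of the defined, finite values, with the number
of excluded infinite/undefined points logged.

## Phylogeny-guided filtering

The Taxon Interaction Mapper rests on one assumption: evolutionarily
related viruses infect evolutionarily related hosts. For every internal
node of a viral marker tree (root excluded — its "rest of the tree" is
empty) and every host taxon seen in the network,
`node_taxon_enrichment()` builds the 2×2 table

|              | associated | not associated |
|--------------|-----------:|---------------:|
| in clade     |  a         |  b             |
| rest of tree |  c         |  d             |

and computes the one-sided Fisher exact p-value `P(X ≥ a)` (hypergeometric
upper tail, log-space `lchoose` sums for stability at large totals — the
test suite pins this to an exact enumeration oracle). A leaf is
"associated with taxon T" if it has at least one retained network edge to
an OTU annotated T; edge weights play no role, the filter is purely
topological. All (node × taxon) p-values are adjusted jointly by
Benjamini–Hochberg; tables with a = 0 are given p = 1 without computation
but stay in the family, so the adjustment is honest about the number of
tests performed. The significance threshold is q < 0.05 (configurable).
`filter_edges_by_enrichment()` then keeps exactly the edges covered by a
significant (node, taxon) pair — a subset of the input, and idempotent —
and `tim_network()` summarizes the result as a family × lineage network
whose weights count enriched nodes, attributing a node to a family only
when its subtree is pure at that family (impure nodes are pooled as
"mixed"; the purity bar is configurable below 100%).

A leaf counts once per taxon regardless of how many edges it has to that
taxon (presence/absence; per-edge counting is available), and BH is
applied jointly across ranks rather than per rank — neither choice is
forced by precedent, both are documented here.

## Virophage analyses

The same enrichment logic applies to virophage–NCLDV networks built on
the virophage major capsid protein (MCP). `assign_clades()` expands
user-specified leaf sets to full MRCA clades (disjointness enforced;
rotation of children cannot change the result), and
`clade_family_enrichment()` tests each (clade, NCLDV family group) for
enrichment of association edges, with families poolable into "Other
NCLDVs". The counting unit is the association edge (OTU-level counting is
available behind a flag — the choice is genuinely ambiguous and edge
counting matches how the networks are drawn). `hgt_candidates()`
implements the horizontal-gene-transfer screen: an MCP whose best hit in
an NCLDV genome database (E ≤ 1e−10, coverage ≥ 50%, identity ≥ 50%)
beats every non-self hit in the MCP database is a candidate; queries with
no non-self guard are reported but flagged.

## The synthetic benchmark

`synth_generate()` produces the whole input bundle with planted truth so
every stage is testable without any external download. Defaults mirror
the study conditions the package targets: 88 samples, 150 eukaryotic
OTUs in 12 major lineages, 100 viral OTUs of which 40% carry a planted
host, per-OTU presence probability 0.5, zero-inflated lognormal
abundances (log-mean 2, log-sd 1).

* **Abundances.** Each host gets a latent Gaussian per sample and a
  Bernoulli presence mask; counts are `round(exp(2 + z))` where present.
  A coupled virus shares its host's presence pattern and its latent is
  correlated through a Gaussian copula calibrated so the Spearman
  correlation over the shared-presence samples is the target
  `coupling_strength` (0.8); at strength 1 and full occupancy the planted
  rank correlation is exactly 1. Rounding ties attenuate this slightly;
  the empirical mean sits within ±0.1 of the target, which the tests
  check.
* **Phylogeny.** The viral tree is a random bifurcating topology.
  Host-lineage preference evolves along it: a node keeps its parent's
  lineage with probability `clade_host_fidelity` per average-length
  branch (switching is a Poisson process along branch lengths, so long
  branches switch more), otherwise it jumps to a random other lineage.
  At fidelity 1 the whole tree is one preference; at 0.5 the labels are
  nearly independent of topology. Infectivity itself is treated as a
  clade trait: coupled viruses are drawn as whole clades (sizes 3–15)
  until the `frac_coupled` quota is met exactly, with random singletons
  topping up the remainder — related viruses infect related hosts, which
  is precisely the signal the phylogeny-guided filter is designed to
  exploit.
* **References and hits.** One reference virus per lineage; coupled
  viruses hit their reference at 66–95% identity with high bitscores,
  and every virus gets decoy hits at 30–60% identity, so the 65%
  grouping threshold separates them cleanly by construction.
* **Environment.** Five meta-variables; temperature confounds a few
  otherwise-uncoupled virus–host pairs (both driven by it through a
  strong copula), giving the conditioning step something real to remove.

What the generator does **not** emulate: spatial/oceanographic structure,
sequence-level evolution, negative or time-lagged couplings (available
behind flags conceptually but off by default, since the validated signal
class is positive co-occurrence), multi-host viruses, and the taxonomic
mis-annotation of real V9 data. Passing the benchmark therefore shows the
machinery is correct and that the method's logic works when its core
assumption holds — not that real marine networks will reach the same
LR+.

## Numerical choices and degenerate inputs

Natural logarithms throughout (clr convention). Constant abundance
profiles make rho undefined: the pair is skipped and counted in a
message. Conditioning variables that are constant or mostly missing are
skipped with a warning. Empty hit tables, empty edge lists and empty
enrichment results flow through as empty tibbles, not errors; an empty
candidate universe or a tree with fewer than 3 leaves is an error.
Fisher p-values are computed in log space and match exact enumeration to
better than 1e−10 relative error for table totals up to 500 (tested).
Unnamed internal tree nodes receive deterministic post-order ids at read
time so that enrichment output is reproducible run to run.

## Problem sizes in the test suite

The shipped tests run the full pipeline at the default generator
conditions (88 samples, 250 OTUs) for seeds 1–5 with 1000 random-predictor
replicates, exhaustively enumerate all 2×2 tables with totals ≤ 24 (plus
1000 random tables with totals ≤ 500) against the Fisher oracle, and use
scaled-down communities (40 samples, 70 OTUs) for the generator's own
property tests. These sizes were chosen to exercise every code path at
full fidelity while keeping the suite comfortably fast on a laptop.

## Known limitations

LR+ judges only how much an edge class concentrates known pairs; with
very few condition positives its variance is large, and at desk scale a
perfect filter often drives the false-positive count to zero, making LR+
infinite — reported as `Inf`, excluded from averages. The partial-rank
conditioning removes single-confounder effects, not arbitrary indirect
paths. The enrichment filter inherits the usual caveat of its assumption:
host switches that cut across the viral phylogeny are invisible to it.
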
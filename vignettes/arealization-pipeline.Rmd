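---
title: "From counts to areal signatures: the cortexatlas pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From counts to areal signatures: the cortexatlas pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexatlas)
```

`cortexatlas` implements the custom computations behind a
developing-cortex arealization atlas as a chain of seedable R functions,
exercised end to end on synthetic data with planted ground truth. This vignette explains
the models and procedures, the parameters that matter, what the
synthetic generator does and does not emulate, and the design choices
made where the methodology left genuine freedom.

## The synthetic atlas generator

`generate_atlas()` draws a negative-binomial gene-by-cell count matrix
whose log mean decomposes additively:

```
log mu[g, c] = log baseline[g]
             + log(FC) * [g is a marker of c's cell type]
             + log(FC) * [g is an areal marker of c's (type, area)]
             + s * log(FC) * [g is an areal marker of c's area in another
                              excitatory-lineage type]   (s = shared_lineage_signal)
             + log(FC) * rank(area) / (K - 1) * [g is a gradient gene]
             + batch[g, individual]
```

with counts `NB(mu, size = dispersion)` so that
`variance = mu + mu^2 / dispersion` — the standard overdispersed noise
model for droplet scRNA-seq. Choices worth knowing:

* **Baselines** are log-normal (median 1 count per cell per gene), giving
  realistic zero fractions at the default depth (2,000 genes, a median of
  roughly 1,000 detected genes per cell).
* **Cell-type programs** default to 20 marker genes per type at fold
  change 4. Real cell types differ by large transcriptional programs;
  twenty genes is deliberately conservative while keeping types
  separable, and it leaves the planted set small enough that top-20
  marker recovery is a meaningful statement.
* **Areal programs** are planted per (cell type, area) with abundance
  increasing along the excitatory lineage (defaults RG = 3, IPC = 5,
  neuron = 8 genes per area), mirroring the biology the pipeline is
  designed to detect: areal identity strengthens as radial glia
  differentiate into neurons. `shared_lineage_signal` (default 0.5) lets
  each lineage type express the other lineage types' areal markers of its
  own area at a reduced log effect — areal signatures detectable in
  progenitors, strongest in neurons.
* **The gradient genes** scale log-linearly with the rostro-caudal area
  rank (PFC lowest, V1 highest), emulating posterior-high/anterior-low
  gradient markers such as *NR2F1*.
* **Batch shifts** are i.i.d. normal per (individual, gene) on the log
  mean (default SD 0.2), a deliberately crude batch model: it justifies
  per-individual clustering and cross-individual merging without
  simulating chemistry- or depth-specific artefacts.
* **Doublets** are exact sums of two random same-individual cells
  (`doublet_rate` appended per individual, parents recorded). Pairing
  ignores cell type, so most doublets are heterotypic — the detectable
  kind. Homotypic doublets, ambient RNA, and empty droplets are *not*
  simulated; passing QC tests here says nothing about those failure
  modes on real data.

All randomness flows from the single `seed` through one sequential draw
order (gene roles and baselines, batch shifts, then per-individual cell
assignments, counts, doublet pairs), so identical configs are
bitwise-reproducible.

The spatial generator `generate_spatial()` emulates a laminar cortical
wall: five zones (VZ to CP) tiling the y-range, nuclei uniform in the
tissue, per-cell spot counts Poisson with a zone-dependent rate, spots
jittered isotropically around their nucleus, optional uniform background
spots, and optional per-cell log-normal rate factors shared within
declared co-expression modules. It does not synthesize images — the
upstream spot detection and nucleus segmentation are out of scope — so
its output is exactly the spot/nucleus tables the quantification stage
consumes.

## Quality control

`filter_cells()` keeps a cell iff it has at least 750 detected genes
(boundary kept), at most 10% mitochondrial counts (boundary kept,
strictly above removed), and a simulated-doublet score below 0.25.
Doublet scoring (`doublet_score()`) is intentionally a simple
reimplementation of the simulated-doublet idea: per capture lane,
synthesize as many artificial doublets as there are observed cells by
summing random pairs, embed observed + simulated cells together
(library-size normalization to 10,000, log1p, top 2,000 variable genes,
30 PCs), and score each cell by the fraction of its 30 nearest
neighbours that are simulated. The score threshold (0.25) and the
filter order (doublets first, then thresholds) are conventions with no
canonical values; both are exposed in `qc_config()`, and with disjoint
failure sets the filters commute anyway (a tested invariant).

## Recursive clustering and cross-individual merging

Each clustering run normalizes, takes the top 2,000 variable genes,
embeds into 50 PCs (truncated SVD with deterministic sign), builds the
15-nearest-neighbour graph with Jaccard weights on shared neighbour
sets, prunes weights at or below 1/15, and maximizes modularity with
seeded Louvain at resolution 1. The kNN search is an exact blocked
brute force with ties broken by cell index — slower than a kd-tree but
bit-reproducible and oracle-checkable, which the test contract demands.
The Jaccard pruning cutoff (1/15) is the conventional
shared-nearest-neighbour default at k = 15; without it, sporadic weak
links between well-separated populations let Louvain absorb boundary
cells into hybrid communities.

The workflow is deliberately recursive and per-individual: level-1
clusters per individual minimize batch effects and keep rare
populations visible; clusters are annotated by a canonical marker panel
(mean-z argmax over the panel genes — canonical-gene annotation has no
single standard algorithm, so the simplest deterministic rule is used); level-2 re-clusters each (individual, cell type) with at
least 50 cells.

Merging bridges batches without any embedding correction: each level-2
cluster gets a **gene-score profile** (its significant up-regulated
markers' gene scores over the union of all marker genes, DE computed
against the cluster's own individual), and clusters whose profiles
correlate at Pearson r >= `merge_threshold` are combined by single
linkage — first within cell types across individuals, then, after
recomputing profiles from the pooled cells, across everything.
`merge_threshold = 0.7` is the single most consequential free parameter
of the whole pipeline: no published default exists, 0.7 is the
package's choice, and `correlate_and_merge()` exposes it (merging is
provably monotone in it, a tested property). Zero-variance profiles
(clusters with no significant markers) are unmergeable by definition
and are kept separate with a warning rather than silently pooled.
Cluster dendrograms use one-minus-Pearson distance on the same profiles
with average linkage; rows are sorted by label first so ties resolve
deterministically, and constant profiles are an error naming the
offending cluster rather than a silent NA.

At the default study conditions (3 individuals x 3,000 cells, 2,000
genes, fold change 4, batch SD 0.2, 5% doublets) the full chain — QC,
recursive clustering, two merge rounds — recovers the six planted cell
types as six level-3 clusters at ARI about 0.97.

## Markers, gene scores, stages

Differential expression is a two-sided Wilcoxon rank-sum test per gene
on normalized log1p expression, Bonferroni-corrected over all features.
Exact enumeration is used when the smaller group has at most 8 cells
*and* the arrangement count is tractable (`choose(N, min) <= 2^21`);
one-vs-rest tests against thousands of complement cells therefore use
the approximation, which carries tie correction, continuity correction
and an Edgeworth kurtosis term (the exact excess kurtosis of the
tie-free null, `-(6/5)(n^2+m^2+nm+N)/(nm(N+1))`) — accurate to a few
1e-3 already at n = m = 8.

Conventions the methodology leaves open are pinned and test-visible:
`avg_logFC = log1p(mean_in) - log1p(mean_out)` on normalized (pre-log)
means; "expressing" means count > 0; `pct_out` is floored at 0.001 in
the enrichment ratio so gene scores stay finite and order-preserving.
Gestational weeks map onto fixed stage bins (early 14/16/17, middle
18/19/20, late 22/25); unsampled weeks are an error, never
interpolated. Dot-plot scaling (`group_scaled_means()`) averages
non-zero cells per group and z-scores across groups with the base-R
`scale()` convention (n - 1 denominator — two groups with means 1 and 3
score -0.707/+0.707); groups with no expressing cells enter as 0 and
are flagged.

`module_eigengene()` scores signature activity as the first principal
component of the standardized expression of the signature genes
expressed in the scored cells, subsampled to at most 10,000 cells, with
the sign oriented along the set's mean standardized expression and unit
variance over scored cells. The acceptance-level recovery check scores
radial glia with 20-gene neuron-derived areal signatures planted as
fully shared along the lineage (`shared_lineage_signal = 1`): the
eigengene then separates V1 radial glia from all others at |r| >= 0.9
against the planted area indicator. With the default half-strength
sharing the correlation is nearer 0.5–0.65 — a faithful reminder that
signature detectability in progenitors depends on how much of the
neuronal program they share, which is exactly the biological quantity
of interest.

## Constellation graphs and the connectivity index

`neighbor_fractions()` pins the directed fraction f(A->B) as the share
of A's pooled neighbour slots (k x |A|) occupied by B cells. Two
natural definitions exist — pooling neighbour slots, or counting cells
with at least one cross-group neighbour — and they differ whenever
group sizes vary; the slot-pooled reading is the default and the
cell-counting variant is available as `mode = "cell"`. Edges require strictly more than the 5%
threshold in at least one direction; end widths are normalized by the
maximum out-of-group fraction over all groups. The connectivity index
multiplies the edge count between two node collections by the mean of
the threshold-passing endpoint fractions on those edges — "mean over
passing endpoint fractions" being the package's resolution of an
ambiguous averaging population, stated here because the absolute scale
of the index depends on it (its zero/symmetry/monotonicity behaviour
does not). Embeddings are inputs, not computed here: UMAP is stochastic
and belongs to the caller; tests and the acceptance script use fixed
synthetic geometries (`simulate_group_coords()`), where chain-adjacent
groups connect and far "pole" groups provably share zero neighbours —
the mutual-exclusivity pattern the index is designed to quantify.

## Signature overlap across stages

`signature_overlap()` is row-normalized: entry (i, j) is the share of
node i's genes found in node j, so the matrix is asymmetric and both
directions together recover the integer intersection exactly (a tested
identity); symmetric Jaccard is an option. Hierarchies cluster the rows
of that matrix by Euclidean distance with average linkage (consistent with the cluster dendrograms).
`sankey_links()` connects only consecutive stages (early->middle,
middle->late) by intersection size — no early->late shortcut even when
the middle stage is absent. Overlap is computed on significant up-regulated markers — the reading
of "marker set" used consistently across the package.

## smFISH quantification

Spots are assigned to the nucleus with the smallest boundary distance
(Euclidean centroid distance minus radius, floored at 0) within
`max_dist` (default 15 um — the platform's actual threshold is
unpublished, so it is config-exposed); equidistant ties go to the lower
nucleus id. Nuclei are circles because the emitted metadata (centroid +
size) supports nothing richer; polygon boundaries would change
distances near touching cells. The "fewer than ten counts" elimination
is read as *cells* with under 10 total assigned spots — a single spot
has no counts to threshold — and the cutoff is a parameter. Laminar
profiles are exact Gaussian-mixture KDEs over y evaluated on a grid
extending 8 bandwidths past the data (so the density integrates to 1 to
numerical precision); a minimum bandwidth of 1 um handles single-spot
degeneracy, and the per-gene quantification scalar is total intensity
over spot count. Co-expression uses Pearson correlation on raw assigned
counts (deliberately unnormalized), inclusive
at r >= 0.05, after excluding POLR2A, SOX2, EOMES and DLX6; a binarized
(detection) mode is available since the validation text speaks of
co-detection frequency.

## Problem sizes, tolerances, determinism

The shipped tests run the full chain at 3 x 3,000 cells x 2,000 genes
(the default study conditions) plus many small oracle fixtures; the
acceptance script uses the same sizes. Numerical contracts worth
restating: exact rank-sum p-values match enumeration oracles to 1e-12;
eigengenes match an explicit SVD to 1e-8 after sign alignment;
neighbour fractions are bit-equal to exhaustive recomputation; all
seeded stages are bitwise reproducible run to run. PCA signs are fixed
by the largest-magnitude loading; kNN and nucleus-assignment ties break
by index; dendrogram ties break by label order.

## Known limitations

The generator's planted programs are block-constant fold changes — no
continuous differentiation trajectories, no depth gradients across
cells, no gene-gene correlation beyond the planted modules — so
recovery results here bound what the pipeline can do under its own
assumptions, not its behaviour on real tissue. The merge stage depends
on marker detectability: at a few hundred cells per individual,
Bonferroni correction leaves small subclusters with empty profiles that
cannot merge (they surface as warnings). RNA-velocity analysis,
UMAP/PCA internals, image processing and cross-dataset comparisons are
intentionally out of scope.
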
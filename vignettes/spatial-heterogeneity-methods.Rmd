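---
title: "Methods: quantifying spatial heterogeneity in multiplexed tissue data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying spatial heterogeneity in multiplexed tissue data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spathet)
```

This vignette documents the models and procedures `spathet` implements, the
parameters that matter, the numerical conventions adopted where a choice had
to be made, and what the synthetic-data generators do and do not emulate.

## Single-cell phenotyping

Raw per-cell mean intensities are rescaled per specimen and marker around a
gate `g` with anchors `m ≤ g ≤ M`: the map sends `[m, g]` linearly to
`[0, 0.5]` and `[g, M]` to `[0.5, 1]`, clipping outside `[m, M]`. Only the
range and the decision point are fixed by the gating convention; the
two-segment piecewise-linear shape is our choice because it preserves
within-class ordering and places the gate exactly at the decision boundary.
Anchors are robust percentiles (0.1th/99.9th by default in
`true_gate_set()`) rather than raw extrema, so single hot pixels cannot
compress the informative range. A value of exactly 0.5 counts as
*negative*: cells expressing a marker are those strictly above 0.5.
A constant channel (`m == M`) maps to 0 everywhere and raises a
degenerate-channel warning rather than an error, since a failed stain
should not abort a run.

Phenotypes are called by an ordered rule hierarchy (`phenotype_hierarchy()`):
each rule lists required positive and negative markers and inherits its
ancestors' requirements; a cell receives the deepest matching rule, ties
going to the earlier rule, and `"unclassified"` otherwise. Tumor cells
(SOX10+) are assigned a differentiation state from the binarized
(MART1, SOX9, NGFR) pattern. The default map — MART1+ alone melanocytic;
MART1+ with SOX9 and/or NGFR transitional; MART1− SOX9+ mesenchymal;
MART1− NGFR+ neural-crest-like — follows the published state vocabulary,
but the exact assignment of mixed patterns is a configuration choice, which
is why `assign_tumor_states()` takes the map as data. The triple-negative
combination is not defined by these three markers; we label it
`"undetermined"` rather than forcing it into a state, and require the map
to stay total over all 8 combinations.

## Delaunay graphs and spatial entropy

The neighbor structure is the Delaunay triangulation of cell centroids
(via `deldir`), with edges weighted by Euclidean distance in microns. All
coordinates are converted to microns at the file boundary (`pixel_size` is
mandatory for pixel inputs) so no downstream quantity depends on
magnification. Duplicate coordinates — impossible under the simulator's
hard-core spacing but possible in real segmentations — are perturbed by
1 μm × 10⁻⁶ with a warning; fewer than three cells or a fully collinear
set is an error. An optional `max_edge` prune (off by default, 50 μm is a
reasonable value) removes the long edges that tumor-only triangulations
draw across stromal gaps; pruning may disconnect the graph, and isolated
nodes then carry zero local entropy with a flag. Exactly cocircular point
sets admit two valid triangulations; either is accepted, and the entropy
statistics are insensitive to the choice except on measure-zero fixtures,
which the tests avoid.

The local Shannon entropy of a cell is the entropy (bits) of the attribute
frequencies among its graph neighbors, the focal cell excluded by default
(`include_focal` reverses this).

The region statistic weights the composition entropy by intermixing. For
attribute `l` among `L` attributes in the analyzed cell set: `n_l` cells,
`p_l = n_l / N`; per cell `i` of attribute `l`, `M_il` counts Delaunay
neighbors with a different attribute and `D_il` sums the edge lengths to
them; `M̄_l` and `D̄_l` are means over the `n_l` cells. Then

```
H = −α · Σ_l (M̄_l / D̄_l) · p_l · log₂(p_l)
```

Conventions adopted here:

* **Sign.** The summand `p_l log₂ p_l` is negative; we negate the sum so
  that `H ≥ 0` and "high entropy" is a large positive number, matching the
  classical Shannon convention. The raw signed value is returned alongside.
* **0/0 guard.** If no cell of attribute `l` has a heterotypic neighbor,
  `M̄_l = D̄_l = 0`; the term is defined as 0, the limit of `M̄/D̄ · term`
  along the generative process as mixing vanishes. Hence `H = 0` exactly
  when `L = 1` or when no heterotypic edge exists.
* **Scope of `p_l`.** Probabilities are computed within the analyzed region
  (the cell set the graph was built on), not the whole specimen, so regions
  are comparable across specimens of different composition.
* **Units and α.** `D̄` is in microns, so `H` is bits·μm⁻¹ at the default
  `α = 1`; doubling all coordinates halves `H` exactly. `α` is a pure
  display scale and never affects comparisons.

`entropy_by_region()` selects cells inside each annotated polygon
(boundary-inclusive point-in-polygon), keeps those with a non-missing
attribute (tumor cells, for state entropy), and builds a fresh graph per
region; regions with fewer than 3 such cells are reported
`"not-computable"` rather than erroring. The optimized implementation is
checked against an independently coded triple-loop transcription of the
definition to 10⁻⁹ on random fixtures up to 200 cells.

Group comparisons delegate to standard routines: two-sided Mann-Whitney U
(`stats::wilcox.test`, exact when both groups have ≤ 8 untied values,
normal approximation with continuity and tie correction otherwise) and
Levene's variance test on absolute deviations from group *means*
(`car::leveneTest(center = mean)` — the classical Levene form; the
median-centered Brown-Forsythe variant is more robust but is not the named
test). At n = 20 per group the mean-centered Levene test holds its nominal
size under normal samples but has moderate power (about three quarters at a
4× variance ratio in our own calibration runs); analysts planning variance
comparisons at this scale should not expect high sensitivity.

## Recurrent cellular neighborhoods

Neighborhood profiles count phenotypes within a fixed radius (default
15 μm — at the 0.3 μm/px scale of the source imagery, 50 px) around each
cell, focal cell excluded so profiles are purely contextual. Clustering
uses *frequencies*, not counts, so local density does not dominate
composition; isolated cells (no neighbor within `r`) are flagged and left
unclustered. k-means runs with 10 restarts under a fixed seed (k-means is
initialization-sensitive; multi-restart plus a recorded seed makes the
labels reproducible). The elbow choice of k maximizes the perpendicular
distance between the inertia curve and its end-point chord; a curve that
ever increases yields status `"no elbow"` instead of a number. RCNs are
grouped into RCNGs by average-linkage agglomeration on correlation distance
between centroids — an algorithmic stand-in for what is in practice a
partly manual curation step, so `rcng_map` can be overridden directly. The
reference-scale defaults (k = 25, g = 11) describe a large cohort; they are
defaults, not recommendations, and small synthetic tissues in our tests use
k of 3–8.

## Invasion bands and proximity

Depth is the Euclidean distance from each centroid to the nearest point of
the annotated epidermis geometry (polyline or polygon; cells inside a
reference polygon get 0). Whether "distance from the epidermis" means
nearest-point distance or perpendicular depth is an open question for
irregular sections; nearest-point is the default because it is defined for
every geometry. Bands are half-open `[k·w, (k+1)·w)` intervals of width
`w = 200` μm, so a cell exactly on a boundary belongs to the deeper band
and band sizes always sum to the cell count. Per-band entropy reuses the
region machinery on the band partition, with the same 3-cell minimum.

Comparative proximity profiles count phenotypes within 15 μm of each focal
cell of two tumor states, aggregate to per-region means, and compare states
per phenotype by rank-sum with Benjamini-Hochberg adjustment across
phenotypes (the source analyses report raw p-values; we add BH because the
phenotype panel makes this a multiple-testing problem). Focal cells with
empty neighborhoods contribute zero vectors rather than being dropped.

## SOM metagene portraits and the correlation spanning tree

Expression preprocessing is log₁₀(x + 1) (the +1 admits zero counts — a
deliberate divergence from bare log₁₀ on filtered data), quantile
normalization across microregions (mean-of-sorted-values with tie
averaging, via `limma`), and gene-wise centering. Zero-variance genes are
retained (centering zeroes them) and flagged.

The SOM treats *genes* as observations in the space of microregions, so
each unit's codebook vector is a metagene — the shared profile of the genes
mapped to it — and a 30 × 30 grid yields exactly 900 metagenes. Training is
a batch SOM: every epoch assigns each gene its best-matching unit, then
replaces every codebook vector by the Gaussian-neighborhood-weighted mean
of all gene profiles, with the neighborhood radius decaying linearly from
half the larger grid side to 1. Initialization spans the first two
principal components of the gene profiles with a deterministic sign
convention, so training involves no randomness at all — the recorded seed
is provenance, not an input. Quantization error is recorded per epoch; it
is not strictly monotone while the radius shrinks, but the end value does
not exceed the start value. With batch effects, fit the SOM per batch (the
metadata carries a `batch` column); codebooks from different batches are
not directly comparable.

Overexpression cluster areas depend on a scaling choice the literature
leaves loose, so `overexpression_clusters()` exposes both readings:
`scale = "profile"` min-max scales each metagene over samples (a unit is
flagged in the samples near its own maximum; constant profiles never flag —
but every non-constant unit flags somewhere, so the union covers the map),
while `scale = "portrait"` scales each sample's portrait over units,
flagging approximately the top 5% of the map per sample at the default
threshold 0.95 — this is the reading that yields discrete cluster areas and
is used for cluster detection. Components use 4-connectivity on the grid.

The correlation spanning tree is the minimum spanning tree under distance
`1 − r` (Pearson) between microregion metagene profiles, built by Kruskal
with edges ordered by weight and then lexicographic node-id pair, so ties
break deterministically. Constant profiles have undefined correlation and
are a contract error naming the offending node. Branch decomposition labels
nodes of degree ≥ 3 as branch points and the connected components of the
remainder as branches. On trees over tens of microregions this rule
fragments finely — every small twig splits a path — so branch labels should
be read as *pure* segments (a branch rarely mixes biologically distinct
arms) rather than as a complete recovery of planted lineages; our tests
assert purity, and a manual override map is accepted for the kind of
interpretive root/branch designation a human makes on the plotted tree.

## The synthetic tissue generator

`simulate_tissue()` emulates the geometry the analysis assumes: an
epidermal keratinocyte band above dermis (surface at `y = 0`), tumor nests
whose stage follows depth (intra-epidermal MIS, dermal RGP above 500 μm,
VGP below), uniform dermal stroma, small endothelial vessels, and clustered
immune infiltrates (60% CD8 T, 20% regulatory T, 20% myeloid). Cells are
placed by compartment-wise Poisson processes with sequential hard-core
inhibition at 4 μm — real nuclei do not overlap, and distinct coordinates
keep the triangulation well-posed. Rejected proposals are re-drawn rather
than discarded, so per-compartment counts remain Poisson with the
configured mean. Default densities (keratinocytes 3000, stroma 800, nests
4000 cells/mm²) and nest radii (70–130 μm) are order-of-magnitude choices
for skin histology, not fits to any dataset.

The planted heterogeneity dial is `theta`: each tumor cell keeps its nest's
dominant state with probability `1 − theta`, otherwise redraws uniformly
from the four states. `theta = 0` gives single-state nests and exactly zero
spatial entropy; the fraction of heterotypic within-nest edges rises
monotonically with `theta`. Marker intensities are two-component
log-normals per marker (negative median 100, positive 1000, log-sd 0.35 —
about tenfold separation, as seen in well-stained channels), so gate-based
phenotype calls on simulated data are near-perfect by construction; the
simulator validates the pipeline's logic, not its robustness to marginal
staining. `simulate_coupled_infiltrate()` anchors immune cluster centres to
nests with probability proportional to `1 + coupling · theta`, giving a
controlled version of the association between local inflammation and tumor
state intermixing; its default per-nest thetas are a shuffled even grid,
with the shuffle drawn from a derived seed so intermixing is independent of
depth and of cell placement.

What the simulator does *not* emulate: nuclear morphology and segmentation
error, staining artifacts and batch drift, spatially varying density
gradients, anisotropic nest shapes, and any registration offset between the
imaging and expression modalities (both are generated in one micron frame —
the same assumption the analysis makes of real data).

`simulate_expression()` generates microregion counts from
`mu = exp(baseline + a_g·progression + b_g·inflammation + batch)` with
negative-binomial noise and sparse loadings: one module up in progression,
one down (melanocytic identity), one up in inflammation, the rest unloaded
background. The `"arms"` design places microregions in three planted
branches (root, progression-only, progression + inflammation), the
structure the spanning tree should partially recover. Quantile
normalization compresses planted signal when loaded genes saturate the
within-sample ranking, so realistic fixtures keep most genes unloaded, as a
whole-transcriptome panel would.

## Problem sizes and numerical tolerances

The test-suite fixtures are sized for a laptop-class single core: tissues
of roughly 600–5000 cells, two to twelve nests, expression matrices up to
about 80 microregions × 400 genes, SOM grids from 6 × 6 to 30 × 30, and
Monte-Carlo calibrations of 20–150 simulated tissues or 1000 statistical
replicates. Exact identities (entropy closed forms, coordinate scaling,
round-trips) are asserted to 10⁻⁹–10⁻¹⁴; Monte-Carlo rates are asserted
through one-sided binomial consistency checks at the simulation's
resolution, since an observed rate sitting exactly at its bound would
otherwise fail half the time by sampling noise alone.

## Known limitations

* The entropy statistic depends on cell density through `D̄` (bits·μm⁻¹);
  compare regions at similar magnification and segmentation quality, or
  prune long edges, before interpreting differences.
* RCNG grouping and CST branch labels are conveniences over genuinely
  interpretive steps; both accept manual overrides and should be reviewed.
* The elbow rule needs a clear inertia knee; on structureless data it
  reports `"no elbow"` or an unstable k.
* All geometry is 2-D; sections are treated as planes and depth bands as
  distances within the section.
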
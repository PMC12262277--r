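# spathet

Spatial heterogeneity analysis for multiplexed tissue imaging and
microregional transcriptomics.

Primary melanomas are mosaics: tumor cells in different differentiation
states — melanocytic, transitional, mesenchymal, and neural-crest-like — sit
side by side within single histologic regions, and the degree of their
spatial intermixing varies from one microregion to the next. `spathet`
provides, for analysts working with high-plex immunofluorescence (e.g.
CyCIF/MCMICRO single-cell tables) and microregional transcriptomics (e.g.
GeoMx digital spatial profiling):

* **Gate-based phenotyping** — per-specimen, per-marker gates rescale raw
  intensities to \[0, 1\] with the gate at 0.5; hierarchical binarized rules
  call cell phenotypes, and a configurable map assigns SOX10+ tumor cells a
  differentiation state from their MART1/SOX9/NGFR pattern.
* **Spatial entropy on Delaunay graphs** — per-cell local Shannon entropy of
  neighbor labels, and a region-level statistic. For attribute *l* with
  *n_l* of *N* cells, *p_l = n_l / N*, intermixing strength
  *M_il* = number of Delaunay neighbors of cell *i* with a different
  attribute and *D_il* = summed Euclidean distance to those neighbors, the
  region statistic is

  *H = −α Σ_l (M̄_l / D̄_l) · p_l log₂ p_l*

  — Shannon entropy of the composition, weighted up by intermixing and down
  by the distance between unlike neighbors (bits·μm⁻¹ at α = 1).
* **Recurrent cellular neighborhoods (RCN)** — radius-based neighborhood
  composition profiles (default 15 μm), k-means clustering (reference-scale
  default k = 25) with elbow-based model choice, and agglomerative grouping
  into RCN groups (default 11).
* **Invasion bands and proximity analysis** — distance-to-epidermis bands of
  0.2 mm, per-band entropy, comparative phenotype composition within 15 μm
  of two focal tumor states, and nearest-neighbor distances between types.
* **SOM metagene portraits and the correlation spanning tree** — a
  deterministic batch SOM (default 30 × 30 grid → 900 metagenes) over
  log-transformed, quantile-normalized, gene-centered expression;
  overexpression cluster areas; a minimum spanning tree on 1 − Pearson
  correlation between microregion metagene profiles, with branch
  decomposition.
* **Simulators** for both data modalities — a marked point-process tissue
  generator with planted state intermixing (`theta`), clustered immune
  infiltrates optionally coupled to intermixing, and a two-latent-factor
  (progression × inflammation) negative-binomial expression generator — so
  the whole pipeline is testable end to end without access to patient data.

## Worked example

Simulate a section with moderate state intermixing, phenotype it from its
raw intensities, and compute per-region spatial entropy:

```r
library(spathet)

sim <- simulate_tissue(tissue_sim_config(seed = 7, theta = 0.5))
sim
#> <tissue_sim: 2602 cells, 6 regions, seed 7>

cells <- rescale_cells(sim$cells, gate_set(true_gate_set(sim)))
cells <- call_phenotypes(cells)
table(cells$phenotype)
#>   CD8 T cell  endothelial       immune keratinocyte      myeloid         Treg
#>           97           56            1          456           32           33
#>        tumor unclassified
#>          570         1357

tumor <- assign_tumor_states(cells[cells$phenotype == "tumor", ])
cells$tumor_state <- NA_character_
cells$tumor_state[match(tumor$cell_id, cells$cell_id)] <- tumor$tumor_state

entropy_by_region(cells, sim$regions)
#>  region_id stage n_cells L          H status
#>       HR01   MIS     240 4 0.09591047     ok
#>       HR02   RGP     106 4 0.07798316     ok
#>       HR03   VGP      81 4 0.08034230     ok
#>       HR04   VGP      53 4 0.07821511     ok
#>       HR05   VGP      89 4 0.08893969     ok
```

Unclassified cells are the simulated dermal stroma (no lineage marker).
Each region's result carries a full audit trail; for the MIS region:

```r
attr(entropy_by_region(cells, sim$regions), "results")[["HR01"]]$components
#>     attribute n_l   p_l M_bar D_bar    term
#>   melanocytic 149 0.621  2.09  34.4 -0.0259
#>   mesenchymal  31 0.129  5.23  85.9 -0.0232
#>       NC-like  28 0.117  5.11  91.5 -0.0202
#>  transitional  32 0.133  4.69  68.2 -0.0266
```

The dominant melanocytic population has few heterotypic neighbors per cell
(M̄ ≈ 2.1) at short range, while the minority states are heavily intermixed
(M̄ ≈ 5); H sums the negated terms, here 0.096 bits·μm⁻¹. With `theta = 0`
every nest is single-state and H = 0 exactly.

`run_pipeline(seed = 1)` chains all stages (simulate → phenotype → entropy →
RCN → bands → proximity → SOM → spanning tree) and returns the stage outputs
plus a provenance manifest.

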
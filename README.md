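# tlsniche

Spatial niche analysis of tertiary lymphoid structures (TLS) in 2D
spatial transcriptomics of inflamed lung.

In allergen-challenged lung, progenitor-like (TCF1⁺/Th0) CD4 T cells
concentrate inside TLS while effector Th2 cells occupy the airways and
parenchyma. Testing that kind of claim quantitatively requires anchoring
every cell to tissue structure. `tlsniche` implements that anchoring for
anyone working with segmented cells-with-coordinates data (e.g. Xenium):

- **TLS polygons** — density-grouped concave hulls (alpha-shape over the
  Delaunay triangulation, circumradius ≤ a concavity length) around
  TLS-zone cells, filtered by minimum area to isolate mature TLS.
- **Distance axes** — per cell, `d_TLS` = distance to the closest TLS
  polygon (0 inside) and `d_bronchi` = mean distance to the 10 nearest
  bronchi-zone cells (0 for members); cells beyond 450 µm are excluded
  from axis analyses.
- **Radial partition** — per TLS, the centroid distance scaled to [0, 1]
  within the TLS; the lowest 50% of the scaled distance is the **core**,
  the rest the **outer** region, and cells within 50 µm outside the edge
  the **surrounding** ring.
- **Axis analyses** — convolved expression profiles (moving average over
  50 cells ordered by axis), expression-weighted 2D kernel densities on
  the `(d_TLS, d_bronchi)` plane, T/B/P region assignment, per-region
  means, and zone marker tests (rank-sum, BH adjustment, pass iff
  adjusted p < 0.05 and |log2FC| > 1 among genes expressed in ≥ 5% of
  both groups).
- **Interactions** — per-zone cell-type × cell-type neighbor-graph edge
  tallies, and a range-gated ligand–receptor score
  `TM₀.₁(ligand | senders within 50 µm of a receiver) ×
  TM₀.₁(receptor | receivers)` with trimmed means.
- **Preprocessing rules** — hashtag demultiplexing (top hashtag ≥ 10
  counts and strictly > 2× the second; doublets excluded), CITE-seq QC
  (≥ 500 RNA counts, ≤ 10% mitochondrial, ≥ 500 surface-tag counts,
  < 2 isotype positives) and spatial QC (≥ 10 transcripts).
- **Zoning** — external zone labels are accepted as-is; a transparent
  neighbor-composition k-means stand-in is provided, plus the capsule
  rule (mean distance to the 5 nearest mesothelial cells ≤ 100 µm).
- **Synthetic tissue generator** — lung-like sections (TLS discs,
  bronchial annuli, vessels, capsule, parenchyma) with per-cell analytic
  truth distances and exponential expression gradients
  `a·e^(−d/λ) + b` in CD4 cells, so every stage is testable end-to-end
  with known ground truth.

## Worked example

```r
library(tlsniche)

cfg <- sim_config(seed = 1L)          # 3 TLS, 2 bronchi, 2 vessels, capsule
tis <- generate_tissue(cfg)
table(tis$cells$true_zone)
#>    bronchi    capsule parenchyma        TLS     vessel
#>        218        341       3377       1154         66

polys <- build_tls_polygons(tis$cells[tis$cells$true_zone == "TLS", ])
sapply(polys, `[[`, "area")
#> [1] 54264 68970 51554          # µm², all above the 5000 µm² filter

d_tls <- distance_to_tls(tis$cells, polys)$d_tls
rad   <- radial_partition(tis$cells, polys, ring_width = 50)
table(rad$category)
#>  core  none outer surrounding
#>   364  3883   729         114
```

The core holds fewer cells than the outer region because the partition
halves the *scaled radial distance*, and cells spread over a disc
concentrate at large radii. Gradients recover the simulated biology: on
the CD4-enriched gradient tissue the convolved *Tcf7* profile along
`d_TLS` has Spearman ρ = −0.97, the convolved *Gata3* profile along
`d_bronchi` has ρ = −0.99, an independent curve fit of counts against
the true distances returns λ̂ = 102 µm (simulated λ = 100 µm), and mean
progenitor expression is 2.1-fold higher in the T region than in P.

The numbered drivers in `analysis/` run the same workflow as a narrated
sequence — `01_simulate.R` through `05_interactions.R` — writing tables
under `results/`; `run_pipeline()` runs everything in one call and its
outputs are byte-identical across reruns of the same config and seed.

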
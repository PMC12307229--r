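# pushscope

Quantification toolkit for how confined ameboid immune cells (dendritic
cells, T cells) coordinate a confinement-induced **central F-actin pool**
with their leading edge. When the path is narrower than the nucleus, these
cells park the nucleus behind the centrosome and assemble an actin pool
between front and nucleus that pushes outward to dilate a path; that central
pool and the lamellipodium compete for a shared actin supply. `pushscope`
implements the image-quantification machinery such a study runs:

- **Pushing-force microscopy** — beads embedded in an elastic agarose layer
  report vertical substrate deformation. Beads are segmented on the Z/time
  maximum projection (with stationarity and aggregate-size filters), reduced
  to Z×T intensity kymographs over a 5×5 px window, and the bead edge distal
  to the coverslip is tracked with a single global Otsu threshold and linear
  sub-step interpolation: `detect_beads()`, `extract_kymograph()`,
  `track_edge()`, `max_displacement()`.
- **Compartment attribution** — per frame, which cell part lies under each
  bead. One-dimensional K-means (k = 3, or k = 2 for pool-deficient cells)
  on the 21×21 px actin intensity trace maps ascending clusters to
  `none`/`cytoplasm`/`central_actin`; a guarded two-way split of the Hoechst
  trace overrides with `nucleus`. Per-region displacements are
  baseline-subtracted against the `none` frames: `classify_frames()`,
  `summarize_region_displacement()`.
- **Single-cell morphometry** — threshold segmentation of cell / central
  pool / nucleus, greedy nearest-centroid track linking with the strict
  \>10-frame filter, center-of-mass speed, protrusion gained/lost-area
  decomposition, background-corrected intensity ratios, MTOC-first
  orientation calls, retraction-event pooling.
- **Temporal coupling** — normalized lagged cross-correlation of per-cell
  series (`r(l)` = Pearson correlation of the overlap at each lag; positive
  lag means the second series follows), with significance of the offset from
  autocorrelation-preserving phase-randomization surrogates:
  `cross_correlate()`, `lag_significance()`, `pool_cross_correlations()`.
- **Constriction profiles** — time-max longitudinal actin density in a
  segmented channel lumen and the inside/outside constriction ratio.
- **Maxima proximity** — local maxima of a matrix-deformation field and an
  actin field within an exact Euclidean neighborhood radius, and directed
  minimum distances per Z-slice and timepoint.

The raw microscopy behind these assays is not publicly deposited, so the
package ships **ground-truthed synthetic scene generators** for every
geometry (`generate_bead_stack()`, `generate_migration_movie()`,
`generate_constriction_movie()`, `generate_field_pair()`); every stage is
validated by recovering quantities the scenes fix by construction.

## Worked example

Simulate a pushing-force scene (20 beads, 0.8 µm push, bead signal-to-noise
5) and run the full pipeline:

```r
library(pushscope)
res <- run_pushforce_pipeline(list(
  seed = 1,
  simulate = list(noise_model = list(gaussian_sd = 20, poisson_on = FALSE))
), out_dir = "results/pushforce")

mean(res$max_displacements$max_displacement_um)
#> [1] 0.7996
aggregate(mean_displacement_um ~ region, res$summary_table, mean)
#>          region mean_displacement_um
#> 1          none                0.000
#> 2     cytoplasm                0.234
#> 3 central_actin                0.784
#> 4       nucleus                0.468
```

The recovered maximum displacement matches the scene's 0.8 µm amplitude; by
construction the deformation is applied under the central pool and sustained
by the nucleus, and the per-region means reproduce that ordering (the
`none` region is zero because it *defines* the baseline; cytoplasm frames
catch the envelope's rise and relaxation).

The coupling analysis on movies whose central pool and protrusion intensity
are anti-correlated (coefficient −0.8, lag 0) recovers the sign in every
cell and the imposed lag on delayed scenes:

```r
res <- run_coupling_pipeline(list(seed = 1, n_cells = 12,
                                  coupling = list(coefficient = -0.8,
                                                  lag_frames = 0)))
res$pooled$mean_r[res$pooled$lag == 0]
#> [1] -0.729
```

The numbered scripts under `analysis/` run each assay end to end
(`01_simulate_scenes.R` … `05_proximity.R`) and write tidy CSV tables under
`results/`. The methods vignette
(`vignettes/pushing-force-quantification.Rmd`) documents the model choices,
defaults and their rationale.

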
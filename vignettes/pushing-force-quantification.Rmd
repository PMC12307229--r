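---
title: "Quantifying pushing forces and actin-pool coordination in confined migrating cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pushing forces and actin-pool coordination in confined migrating cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pushscope)
```

## The biological measurement problem

Ameboid immune cells such as dendritic cells squeeze through gaps narrower
than their own nucleus. When they do, they assemble a *central actin pool*
between the leading edge and the nucleus that pushes outward against the
confining material, dilating a path, and this central pool competes with the
lamellipodium for a shared actin supply. `pushscope` implements the
quantification machinery such a study needs:

1. **Pushing-force microscopy** — fluorescent beads embedded in an agarose
   layer report vertical substrate deformation as cells migrate beneath
   them. We track each bead's intensity edge along Z through time.
2. **Compartment attribution** — which part of the cell (nothing, cytoplasm,
   central actin pool, nucleus) sits under a bead at each frame, so that
   deformation can be attributed per compartment.
3. **Shape/intensity morphometry** of single migrating cells in 2D:
   segmentation, track linking, center-of-mass speed, protrusion (gained /
   lost area) decomposition, background-corrected intensity ratios,
   MTOC-first orientation calls, retraction-event pooling.
4. **Temporal cross-correlation** of per-cell series (central-pool actin,
   protrusion actin, speed, area) with a significance test for the offset.
5. **Constriction profiles** — actin enrichment inside microchannel
   constrictions from time-max longitudinal density profiles.
6. **Maxima proximity** — distances between local maxima of a matrix
   deformation field and of actin intensity.

Because the assays' raw microscopy is not publicly deposited, the package
ships a synthetic-scene generator with exact ground truth for each geometry;
every stage is validated against scenes whose answers are known by
construction.

## The bead-displacement readout

A bead is a sub-resolution fluorophore-filled sphere (nominally 1 µm); we
render and analyse it as a 3D Gaussian because the analysis tracks an
intensity *edge*, not sphere geometry. The pipeline follows four steps:

* **Detection.** Beads are segmented on the Otsu-thresholded maximum
  projection over Z and time. Components larger than `max_area_px` are bead
  aggregates, smaller than `min_area_px` noise; a component whose per-frame
  centroid wanders more than `stationarity_max_shift_px` (default 2 px) from
  its time mean is nonstationary (a floating bead), and beads too close to
  the border to support the analysis windows are dropped. Every rejection is
  recorded with its reason.
* **Kymograph.** For each accepted bead, the mean intensity over a 5×5 px XY
  window, for every Z and T — a Z×T image in which the bead is a bright
  horizontal band that bulges upward when the cell passes. The mean (not the
  sum) keeps kymograph units independent of the window size.
* **Edge tracking.** One *global* Otsu threshold on the whole kymograph
  (per-frame thresholds jitter with noise), then per frame the Z position
  where the profile crosses the threshold on the side away from the
  coverslip — the cell pushes beads away from it — located with linear
  sub-step interpolation. Frames that never cross are flagged invalid rather
  than guessed.
* **Baseline.** Displacement is the edge minus the bead's *no-cell* baseline:
  the mean edge over frames later classified `none`. Before labels exist,
  the first and last three valid frames stand in.

Two numerical choices matter at realistic noise. At a bead-peak
signal-to-noise ratio of 5, raw threshold-crossing jitter is of the same
order as the 0.1 µm z-step, so `track_edge()` smooths the kymograph along Z
with a 1-z-step Gaussian and passes the edge series through a 3-frame
temporal median. Both are symmetric and bias-free on any displacement
plateau of three or more frames; the synthetic envelope holds its plateau at
least that long so the recovered maximum is a sustained feature, not a noise
excursion. With these defaults, 20 synthetic beads pushed 0.8 µm at SNR 5
are all recovered within ±0.05 µm (see `tests/testthat/test-acceptance.R`
and `scripts/acceptance.R`, which recompute this).

## Compartment classification

The actin and nucleus (Hoechst) intensities are summed per frame over a
21×21 px window around each bead (the assay's 20×20 px volume, centered).
`classify_frames()` runs one-dimensional K-means on the actin trace with
k = 3 for cells with a central pool (`none` < `cytoplasm` < `central_actin`
by ascending cluster mean) or k = 2 for pool-deficient cells, with a fixed
seed and 10 restarts. Frames in the upper cluster of a two-way split of the
nucleus trace are relabeled `nucleus`, overriding the actin label — the
nucleus sustains deformations and is reported as its own region even though
actin is present beneath it.

Plain K-means always splits its input, so a bead that no cell ever visits
would get arbitrary `none`/`cytoplasm`/`central_actin` labels from pure
noise. Both the cluster mapping and the nucleus override are therefore
guarded by a separation requirement: a cluster is kept distinct only when
its mean exceeds the next-lower cluster's by more than 3× the trace's
frame-to-frame noise scale, estimated as the median absolute deviation of
successive differences over √2. That estimator sees only the noise, not the
plateau structure, so genuinely separated intensity regimes (≥ 5 sd apart)
are untouched while a featureless trace collapses to all-`none`. Clustering
is per bead, because absolute intensities vary bead-to-bead with depth; a
pooled variant can be had by concatenating traces. Single-frame label
flickers are absorbed into the neighboring run (minimum dwell 2 frames at
30 s sampling, against multi-minute passage events).

Per-region displacement is then the mean tracked edge over the region's
frames minus the `none` baseline, so the `none` region is zero by
construction and regions with no frames are absent rather than zero.

## Morphometry and coupling

`segment_cell()` is a deliberately simple stand-in for a trained pixel
classifier: Gaussian smoothing, Otsu on *log* intensities (the cell occupies
a small area fraction with several brightness tiers — on a linear histogram
the bright organelle pixels hijack the split), largest connected component.
The central pool is the largest component above a second Otsu threshold of
the in-cell intensities that avoids both the cell boundary band and the
lamellipodial rim. Externally produced masks can be supplied everywhere and
bypass this entirely.

`link_tracks()` replaces a full tracking suite with greedy nearest-centroid
linking under a 20 px/frame gate — tracking is only used to isolate
non-interacting cells, not to resolve crossings. Masks that touch, and masks
claimed as nearest by two track heads (a merge), terminate the tracks
involved. Tracks must be strictly longer than ten frames to survive, and the
filter is deliberately strict: a ten-frame track dies, an eleven-frame track
lives.

For the coupling analysis the central-pool series is the background-
corrected integrated actin inside the pool mask. The protrusion series is
integrated over the *leading-edge rim band* of the segmentation (rim depth =
the lamellipodium depth, front half selected by the centroid's motion
direction). An alternative — integrating over the one-frame gained region —
turns out to measure the *growth rate* of the protrusion rather than its
actin content, because the gained area is the discrete derivative of the
front extension; on scenes with known coupling it shifts the correlation
peak and can flip the sign of r(0). The gained/lost decomposition itself
(`protrusion_regions()`) is still the exact set difference of consecutive
masks, with the area identity `area(t+1) − area(t) = gained − lost` holding
exactly.

`cross_correlate()` computes, per lag, the Pearson correlation of the
overlapping segments, each normalized on its own overlap so every value is a
true correlation in [−1, 1]; positive lag means the second series follows
the first. Moving-median detrending is available but off by default.
`lag_significance()` tests the maximum |r| over lags against
autocorrelation-preserving surrogates of the second series. Two nulls are
implemented. Circular shifting (offsets of at least `max_lag` + 1, so no
shift/lag pair can undo the permutation) is the classic construction, but
excluding the shifts nearest the observed alignment leaves its null
under-dispersed: in our calibration at n = 200 and max_lag = 10 it rejects
independent pairs at roughly 0.07–0.08 instead of 0.05, while sampling the
full circle calibrates exactly but lets a perfectly coupled pair escape the
p-value floor. Fourier phase randomization keeps the entire autocovariance,
attains the floor, and calibrates at 0.045–0.053 on both white and smoothed
series in the same runs — it is therefore the default, with the circular
null available as `method = "circular"`.

## Constriction profiles and maxima proximity

The channel lumen is segmented from brightfield (threshold + largest
component + hole filling) or supplied directly. The longitudinal density
profile is the per-column *mean* over lumen pixels — invariant to the lumen
height — per frame; the time-max projection of these profiles gives the
final profile, and the enrichment ratio is its maximum inside the
constriction interval over its maximum outside. Intervals are half-open,
0-based pixel columns for unambiguous bookkeeping. A per-column background
(median over stated cell-free frames) can be subtracted first.

`local_maxima()` retains pixels that are maxima of their exact Euclidean
radius-neighborhood and exceed a prominence threshold above the field median
(default 3× the field's MAD; a study should set it explicitly), with
non-maximum suppression ordered by value and then lexicographic position, so
retained maxima are always more than one radius apart. Distances are
directed deformation → actin per Z-slice and timepoint; slices without
counterpart maxima are flagged absent, not infinite, and a symmetric variant
exists behind a flag.

## The synthetic scenes: what they emulate, and what they do not

The generators are test harnesses with exact bookkeeping, not biophysical
models:

* **Bead scenes** place beads in a corridor that a cell footprint (cytoplasm
  disc, bright central pool, trailing nucleus) fully crosses, so every bead
  has genuine no-cell epochs at both ends. A bead's true vertical position
  is `baseline + amplitude × envelope(t)`: the envelope rises over three
  frames while the cell body approaches, holds exactly 1 (for at least three
  frames) while the pool or nucleus covers the bead, and relaxes *within*
  the overlap window — during nuclear exit — so that no bead is ever
  displaced on a frame with no cell above it. The true maximum displacement
  therefore equals the amplitude exactly. Defaults mirror the acquisition:
  0.1 µm z-steps, 30 s frames, 0.16 µm pixels, 0.8 µm amplitude.
* **Migration movies** drive a disc cell with a lamellipodial front band and
  a central pool whose latent intensity series are constructed with an exact
  coupling coefficient and lag; the front outline extends and retracts with
  the protrusion latent (≈1.5 µm per latent unit), since with a rigid
  outline no segmentation-based readout could see the latent at all, and
  front actin accumulation and protrusion growth go together in the system
  being emulated.
* **Constriction movies** translate a cell segment through a lumen whose
  in-constriction signal is exactly `enrichment_factor` times the outside
  plateau; noise is confined to the lumen so masked-out pixels stay exactly
  at background.
* **Field pairs** place isolated Gaussian bumps with the paired maxima
  offset by a whole-pixel displacement, so the true separation is exact.

Real data differ in ways these scenes do not probe: uneven illumination and
bleaching, anisotropic PSFs, bead aggregates that overlap cells, cells that
change shape far more irregularly, segmentation errors that correlate with
signal. Passing the synthetic recovery tests shows the *computations* are
correct and calibrated at realistic noise; it does not certify performance
on any particular microscope's data. All scenes are deterministic given a
seed (one stream per scene, sub-streams per channel), and identical
configurations reproduce identical result tables byte for byte.

## Problem sizes and defaults used in the shipped analyses

The bundled analyses and acceptance checks use: 20-bead scenes of
40×32×96×360 voxels (SNR 5) for the pushing-force recovery; 50 simulated
cells of 80 frames for the r(0) sign check; 500 independent pairs × 1000
surrogates for the type-I calibration; enrichment factors {2, 3, 5} under
default noise; and 6-peak field pairs at a 2 µm offset. These sizes make
each property estimate stable while keeping a full run in minutes on a
single core.

File formats: stacks are written as plain multi-page 32-bit float TIFF
(pages ordered T, Z, C) with a JSON sidecar carrying axes, shape, channel
names, calibrations and intensity scaling; `read_stack()` also accepts
arbitrary multi-page TIFFs with an explicit axis specification. Result
tables are tidy CSV, one row per entity and frame.

## Known limitations

* The threshold-based segmentation stand-ins are honest but simple; data
  with textured backgrounds need externally supplied masks (all functions
  accept them).
* The nearest-centroid linker does not resolve cell crossings; it is meant
  to discard them.
* The classifier's separation guard assumes the trace noise is roughly
  stationary; slow drifts larger than the class separation would defeat it.
* The displacement envelope is a smooth bump, not a mechanical model of
  agarose elasticity; no statement about absolute forces is made anywhere —
  the readout is deformation, in micrometers.
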
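#!/usr/bin/env Rscript
# Central-pool / protrusion coupling: simulate anti-correlated migration
# movies, segment and track each cell, extract background-corrected actin
# series for the central pool and the leading edge, cross-correlate them per
# cell and pool across cells.  Also runs a lag-recovery scene and the
# permutation significance test on one cell.

library(pushscope)

out <- "results/coupling"
res <- suppressWarnings(run_coupling_pipeline(
  list(seed = 1L, n_cells = 12L,
       coupling = list(coefficient = -0.8, lag_frames = 0L),
       significance = list(enabled = TRUE, n_permutations = 1000L)),
  out_dir = out))

cs <- res$cell_summary
message(nrow(cs), " cells analysed")
message("pooled r(0): ",
        round(res$pooled$mean_r[res$pooled$lag == 0L], 3),
        "  (cells with negative r(0): ", sum(cs$r_lag0 < 0), "/", nrow(cs), ")")
message("median permutation p for the offset: ", stats::median(cs$p_value))

lagres <- suppressWarnings(run_coupling_pipeline(
  list(seed = 2L, n_cells = 6L,
       coupling = list(coefficient = -0.8, lag_frames = 3L))))
pooled <- lagres$pooled
message("lag-3 scene: pooled |r| peaks at lag ",
        pooled$lag[which.max(abs(pooled$mean_r))], " (truth 3)")
message("tables written to ", out)
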
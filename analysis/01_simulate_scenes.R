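#!/usr/bin/env Rscript
# Generate one compact synthetic scene of each assay geometry, write the
# stacks under scratch/scenes/ (raw rasters are working data, not results)
# and record what the ground truth holds.  Downstream analysis scripts
# regenerate their scenes from seeds, so this step is illustrative: it shows
# what the raw inputs look like on disk.

library(pushscope)

out <- "scratch/scenes"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1L

message("Bead-displacement Z-stack (pushing-force microscopy geometry) ...")
bead_scene <- generate_bead_stack(bead_scene_params(
  image_shape = c(t = 12L, z = 32L, y = 48L, x = 170L),
  n_beads = 2L, cell_speed_um_per_s = 0.17, seed = seed))
write_stack(bead_scene$stack, file.path(out, "bead_scene.tif"))
message("  beads: ", nrow(bead_scene$truth$bead_xy_px),
        "; true max displacement: ",
        max(bead_scene$truth$displacement_um), " um")

message("Under-agarose migration movie with coupled actin pools ...")
mig <- generate_migration_movie(
  migration_scene_params(image_shape = c(t = 30L, y = 90L, x = 120L),
                         cell_speed_um_per_s = 0.01),
  coupling_coefficient = -0.8, coupling_lag_frames = 0L, seed = seed)
write_stack(mig$stack, file.path(out, "migration_movie.tif"))
message("  latent protrusion/central correlation at lag 0: ",
        round(stats::cor(mig$truth$latent_protrusion,
                         mig$truth$latent_central), 3))

message("Constricted-channel passage movie ...")
con <- generate_constriction_movie(enrichment_factor = 3, seed = seed)
write_stack(con$stack, file.path(out, "constriction_movie.tif"))
message("  constriction interval (0-based, half-open): ",
        paste(con$truth$constriction_interval_px, collapse = "-"))

message("Paired deformation / actin fields ...")
fp <- generate_field_pair(6, 6, offset_um = 2, pixel_size_um = 0.5,
                          field_shape = c(y = 100L, x = 100L), seed = seed)
utils::write.csv(data.frame(field = "deformation",
                            fp$truth$deformation_maxima_px),
                 file.path(out, "field_truth_maxima.csv"), row.names = FALSE)
message("  true pair offset: ", unique(fp$truth$pair_offset_um), " um")

message("done; stacks under ", out)
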
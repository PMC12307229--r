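# Ground-truth contracts of the scene generators.

test_that("bead scenes are deterministic in the seed and noise responds to it", {
  p <- small_bead_params(image_shape = c(t = 10L, z = 30L, y = 48L, x = 150L),
                         n_beads = 2L, cell_speed_um_per_s = 0.12)
  a <- generate_bead_stack(p)
  b <- generate_bead_stack(p)
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth$bead_z_um, b$truth$bead_z_um)
  p2 <- small_bead_params(image_shape = c(t = 10L, z = 30L, y = 48L, x = 150L),
                          n_beads = 2L, cell_speed_um_per_s = 0.12, seed = 99L)
  c <- generate_bead_stack(p2)
  expect_false(identical(a$stack$channels$bead, c$stack$channels$bead))
})

test_that("displacement envelope is exact: zero amplitude and amplitude/z-step", {
  p0 <- small_bead_params(displacement_amplitude_um = 0,
                          noise_model = list(gaussian_sd = 0, poisson_on = FALSE))
  sc0 <- generate_bead_stack(p0)
  expect_true(all(sc0$truth$bead_z_um == p0$bead_baseline_z_um))

  p <- small_bead_params(noise_model = list(gaussian_sd = 0, poisson_on = FALSE))
  sc <- generate_bead_stack(p)
  spans <- apply(sc$truth$bead_z_um, 1L, function(v) max(v) - min(v))
  # every bead is passed over, so span = amplitude = 8 z-steps exactly
  expect_equal(spans, rep(0.8, p$n_beads))
  expect_equal(spans / p$voxel_size_um[["z"]], rep(8, p$n_beads))
})

test_that("noiseless scenes reproduce the recorded truth when re-measured", {
  p <- small_bead_params(n_beads = 3L,
                         noise_model = list(gaussian_sd = 0, poisson_on = FALSE))
  sc <- generate_bead_stack(p)
  vz <- p$voxel_size_um[["z"]]
  for (i in seq_len(3L)) {
    iy <- round(sc$truth$bead_xy_px[i, "y"])
    ix <- round(sc$truth$bead_xy_px[i, "x"])
    for (t in c(1L, which.max(sc$truth$displacement_um[i, ]))) {
      prof <- sc$stack$channels$bead[t, , iy, ix]
      z_meas <- (which.max(prof) - 0.5) * vz
      expect_lt(abs(z_meas - sc$truth$bead_z_um[i, t]), vz / 2 + 1e-9)
    }
  }
})

test_that("background noise variance grows monotonically with gaussian_sd", {
  shp <- c(t = 4L, z = 30L, y = 48L, x = 150L)
  vars <- vapply(c(1, 5, 15), function(s) {
    sc <- generate_bead_stack(small_bead_params(
      image_shape = shp, n_beads = 1L, cell_speed_um_per_s = 0.35,
      noise_model = list(gaussian_sd = s, poisson_on = FALSE)))
    stats::var(as.numeric(sc$stack$channels$bead[1L, 27:30, 1:10, 1:10]))
  }, numeric(1))
  expect_true(all(diff(vars) > 0))
})

test_that("undersized bead scenes raise a parameter error", {
  expect_error(generate_bead_stack(small_bead_params(
    image_shape = c(t = 4L, z = 4L, y = 48L, x = 150L))), "too small")
})

test_that("migration latents honor the requested coupling and lag", {
  mm <- generate_migration_movie(coupling_coefficient = -1,
                                 coupling_lag_frames = 0L, seed = 5L)
  expect_equal(stats::cor(mm$truth$latent_protrusion, mm$truth$latent_central), -1)

  p <- migration_scene_params(image_shape = c(t = 400L, y = 70L, x = 70L),
                              cell_speed_um_per_s = 0)
  mm3 <- generate_migration_movie(p, coupling_coefficient = -0.8,
                                  coupling_lag_frames = 3L, seed = 6L)
  zp <- mm3$truth$latent_protrusion; zc <- mm3$truth$latent_central
  # independent oracle: plain lagged Pearson correlations of the latents
  lags <- -8:8
  r <- vapply(lags, function(l) {
    n <- length(zp)
    if (l >= 0) stats::cor(zp[1:(n - l)], zc[(1 + l):n]) else
      stats::cor(zp[(1 - l):n], zc[1:(n + l)])
  }, numeric(1))
  expect_equal(lags[which.max(abs(r))], 3L)
  expect_lt(r[lags == 3L], -0.6)
})

test_that("a stationary cell keeps a constant centroid path", {
  p <- migration_scene_params(image_shape = c(t = 20L, y = 70L, x = 70L),
                              cell_speed_um_per_s = 0)
  mm <- generate_migration_movie(p, 0.5, 0L, seed = 2L)
  expect_equal(max(apply(mm$truth$cell_centroid_px, 2L, function(v) diff(range(v)))), 0)
})

test_that("degenerate migration scenes error", {
  p <- migration_scene_params(image_shape = c(t = 12L, y = 40L, x = 40L))
  expect_error(generate_migration_movie(p, -0.5, 3L, seed = 1L), "degenerate")
})

test_that("constriction movies encode the enrichment factor exactly", {
  p0 <- constriction_scene_params(noise_model = list(gaussian_sd = 0))
  m1 <- generate_constriction_movie(p0, enrichment_factor = 1, seed = 1L)
  tm <- apply(m1$stack$channels$actin[, 1L, , ], c(2L, 3L), max)  # time-max image
  prof <- colSums(tm * m1$channel_mask) / colSums(m1$channel_mask)
  expect_equal(diff(range(prof, na.rm = TRUE)), 0)       # flat in-channel profile

  m3 <- generate_constriction_movie(p0, enrichment_factor = 3, seed = 1L)
  tm3 <- apply(m3$stack$channels$actin[, 1L, , ], c(2L, 3L), max)
  prof3 <- colSums(tm3 * m3$channel_mask) / colSums(m3$channel_mask)
  ci <- m3$truth$constriction_interval_px
  inside <- prof3[(ci[1L] + 1L):ci[2L]]
  outside <- prof3[-((ci[1L] + 1L):ci[2L])]
  expect_equal(mean(inside) / mean(outside, na.rm = TRUE), 3)
})

test_that("masked-out constriction pixels are exactly background", {
  m <- generate_constriction_movie(enrichment_factor = 3, seed = 2L)
  out <- !m$channel_mask
  for (t in c(1L, 15L)) {
    fr <- m$stack$channels$actin[t, 1L, , ]
    expect_true(all(fr[out] == 0))
  }
})

test_that("constriction interval outside the image errors", {
  expect_error(constriction_scene_params(constriction_interval_px = c(150L, 260L)),
               "outside image")
})

test_that("field pairs place maxima at the exact requested offset", {
  fp0 <- generate_field_pair(3, 3, offset_um = 0, seed = 3L)
  expect_equal(fp0$truth$deformation_maxima_px, fp0$truth$actin_maxima_px)

  fp <- generate_field_pair(4, 4, offset_um = 2, pixel_size_um = 0.5, seed = 4L)
  expect_equal(unname(fp$truth$pair_offset_um), rep(2, 4))
  expect_false(fp$truth$warn_close)

  fp_empty <- generate_field_pair(3, 0, offset_um = 2, seed = 5L)
  expect_equal(nrow(fp_empty$truth$actin_maxima_px), 0L)
})
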
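# Segmentation, track linking, speed, protrusion decomposition, intensity
# ratios, orientation calls and retraction-event pooling.

test_that("segment_cell recovers generator masks and tolerates blank frames", {
  mm <- generate_migration_movie(coupling_coefficient = 0,
                                 coupling_lag_frames = 0L, seed = 9L)
  t <- 10L
  fr <- mm$stack$channels$actin[t, 1L, , ]
  nf <- mm$stack$channels$nucleus[t, 1L, , ]
  seg <- segment_cell(fr, nf)
  jac <- function(a, b) sum(a & b) / sum(a | b)
  expect_gte(jac(seg$cell, mm$truth$masks$cell[[t]]), 0.8)
  expect_gte(jac(seg$nucleus, mm$truth$masks$nucleus[[t]]), 0.8)
  expect_gte(jac(seg$pool, mm$truth$masks$pool[[t]]), 0.5)
  expect_false(any(seg$pool & !seg$cell))

  blank <- segment_cell(matrix(0, 40, 40), matrix(0, 40, 40))
  expect_false(any(blank$cell) || any(blank$pool) || any(blank$nucleus))
})

test_that("track linking follows one cell and applies the strict >10 filter", {
  path20 <- lapply(1:20, function(t) cbind(30, 5 + 2 * t))
  tracks <- link_tracks(disc_label_frames(path20, nX = 60L))
  expect_equal(length(tracks), 1L)
  expect_equal(length(tracks[[1L]]$frames), 20L)

  path10 <- lapply(1:10, function(t) cbind(30, 8 + 2 * t))
  expect_equal(length(link_tracks(disc_label_frames(path10, nX = 40L))), 0L)
  path11 <- lapply(1:11, function(t) cbind(30, 8 + 2 * t))
  expect_equal(length(link_tracks(disc_label_frames(path11, nX = 40L))), 1L)
})

test_that("merging cells terminate both tracks at the merge frame", {
  # two discs approach for 14 frames, fuse into one mask afterwards
  centers <- lapply(1:20, function(t) {
    gap <- max(0, 16 - t)
    if (gap > 6) rbind(c(30, 30 - gap), c(30, 30 + gap)) else cbind(30, 30)
  })
  tracks <- link_tracks(disc_label_frames(centers, nX = 60L),
                        min_track_frames = 5L)
  ends <- sort(vapply(tracks, function(tr) max(tr$frames), numeric(1)))
  starts <- vapply(tracks, function(tr) min(tr$frames), numeric(1))
  expect_true(all(ends[starts == 1] <= 9))   # both original tracks end pre-merge
})

test_that("cell speed follows the centroid arithmetic and the generator", {
  tr <- structure(list(frames = 1:5,
                       centroid_px = cbind(y = rep(10, 5), x = seq(0, 8, by = 2)),
                       area_px = rep(50, 5), labels = rep(1L, 5),
                       pixel_size_um = 0.5, frame_interval_s = 30),
                  class = "cell_track")
  sp <- cell_speed(tr)
  expect_equal(sp$mean_um_per_min, 2)
  tr$centroid_px <- cbind(y = rep(10, 5), x = rep(3, 5))
  expect_equal(cell_speed(tr)$mean_um_per_min, 0)
  tr$centroid_px <- tr$centroid_px[1L, , drop = FALSE]
  expect_error(cell_speed(tr), "short")

  # rigid generator cell at a known speed
  p <- migration_scene_params(image_shape = c(t = 30L, y = 90L, x = 200L),
                              protrusion_extension_um = 0,
                              cell_speed_um_per_s = 0.04)
  mm <- generate_migration_movie(p, 0, 0L, seed = 3L)
  labs <- lapply(seq_len(30L), function(t) {
    m <- matrix(0L, 90L, 200L); m[mm$truth$masks$cell[[t]]] <- 1L; m
  })
  tks <- link_tracks(labs, pixel_size_um = p$pixel_size_um,
                     frame_interval_s = p$frame_interval_s)
  expect_equal(length(tks), 1L)
  v_true <- 0.04 * 60
  expect_lt(abs(cell_speed(tks[[1L]])$mean_um_per_min - v_true) / v_true, 0.05)
})

test_that("protrusion decomposition equals brute-force set differences", {
  sq <- matrix(FALSE, 20L, 20L); sq[6:15, 6:15] <- TRUE
  sh <- matrix(FALSE, 20L, 20L); sh[6:15, 9:18] <- TRUE
  pr <- protrusion_regions(sq, sh, pixel_size_um = 1)
  expect_equal(pr$gained_area_um2, 30)
  expect_equal(pr$lost_area_um2, 30)

  same <- protrusion_regions(sq, sq)
  expect_equal(same$gained_area_um2, 0)
  expect_equal(same$lost_area_um2, 0)

  none <- matrix(FALSE, 20L, 20L)
  pr2 <- protrusion_regions(none, sh)
  expect_equal(pr2$gained_area_um2, sum(sh))
  expect_equal(pr2$lost_area_um2, 0)

  set.seed(10)
  for (i in 1:25) {
    a <- matrix(stats::runif(400) > 0.5, 20L)
    b <- matrix(stats::runif(400) > 0.5, 20L)
    pr <- protrusion_regions(a, b)
    expect_identical(pr$gained_mask, b & !a)
    expect_identical(pr$lost_mask, a & !b)
    expect_false(any(pr$gained_mask & pr$lost_mask))
    # area conservation identity, exact
    expect_identical(sum(b) - sum(a),
                     as.integer(pr$gained_area_um2 - pr$lost_area_um2))
  }
})

test_that("integrated intensity is background-anchored and offset-invariant", {
  fr <- matrix(3, 30L, 30L)
  mask <- matrix(FALSE, 30L, 30L); mask[5:14, 5:14] <- TRUE
  expect_equal(integrated_intensity(fr, mask), 0)
  fr2 <- fr; fr2[mask] <- 8
  expect_equal(integrated_intensity(fr2, mask), 500)
  expect_equal(integrated_intensity(fr2 + 11.5, mask), 500)
  expect_error(integrated_intensity(fr, matrix(FALSE, 30L, 30L)), "empty")
  expect_warning(v <- integrated_intensity(fr - 5, mask, background_estimate = 3),
                 "clipped")
  expect_equal(v, 0)
})

test_that("normalized central intensity matches its closed forms", {
  cell <- matrix(FALSE, 40L, 40L); cell[11:30, 11:30] <- TRUE
  pool <- matrix(FALSE, 40L, 40L); pool[18:23, 18:23] <- TRUE
  uniform <- matrix(0, 40L, 40L); uniform[cell] <- 10
  nc <- normalized_central_intensity(list(uniform, uniform),
                                     list(cell, cell), list(pool, pool))
  expect_equal(nc$per_frame, c(1, 1))
  expect_equal(nc$track_mean, 1)

  # pool at 3x the cell-wide per-pixel mean
  np <- sum(pool); ncell <- sum(cell)
  b <- 27 * (ncell - np) / (ncell - 3 * np)    # solve b = 3 * mean(cell)
  fr3 <- matrix(0, 40L, 40L); fr3[cell] <- 9; fr3[pool] <- b
  nc3 <- normalized_central_intensity(list(fr3), list(cell), list(pool))
  expect_equal(nc3$track_mean, 3, tolerance = 1e-12)
  # gain invariance
  nc3g <- normalized_central_intensity(list(fr3 * 2), list(cell), list(pool))
  expect_equal(nc3g$track_mean, nc3$track_mean)
})

test_that("lamellipodium density fraction matches the two-compartment form", {
  cell <- matrix(FALSE, 40L, 40L); cell[11:30, 11:30] <- TRUE   # 400 px
  lam <- matrix(FALSE, 40L, 40L); lam[11:12, 11:30] <- TRUE     # 10% of cell
  fr <- matrix(0, 40L, 40L); fr[cell] <- 5; fr[lam] <- 10       # 2x density
  expect_equal(lamellipodium_fraction(fr, lam, cell), 2 / 1.1)
  expect_equal(lamellipodium_fraction(fr * 3.2, lam, cell), 2 / 1.1)
  uni <- matrix(0, 40L, 40L); uni[cell] <- 7
  expect_equal(lamellipodium_fraction(uni, lam, cell), 1)
  expect_error(lamellipodium_fraction(fr, lam, matrix(FALSE, 40L, 40L)), "empty")
  outside <- lam; outside[1L, 1L] <- TRUE
  expect_error(lamellipodium_fraction(fr, outside, cell), "outside")
})

test_that("orientation calls are antisymmetric with a one-pixel tie zone", {
  call <- classify_orientation(c(10, 25), c(10, 20), axis_vector = c(0, 1),
                               pixel_size_um = 0.4)
  expect_equal(call$value, "mtoc_first")
  expect_equal(call$projection_um, 5 * 0.4)
  expect_false(call$tie)

  flip <- classify_orientation(c(10, 25), c(10, 20), axis_vector = c(0, -1))
  expect_equal(flip$value, "nucleus_first")

  tie <- classify_orientation(c(10, 20), c(10, 20), axis_vector = c(0, 1))
  expect_true(tie$tie)
  expect_equal(tie$value, "nucleus_first")

  expect_error(classify_orientation(c(1, 1), c(0, 0), axis_vector = c(0, 0)),
               "zero axis")
})

test_that("retraction events pool onto normalized, onset-aligned curves", {
  ev <- list(list(intensity = c(2, 2, 2, 2), onset = 2L),
             list(intensity = c(5, 5, 5, 5), onset = 2L))
  agg <- pool_retraction_events(ev)
  expect_true(all(agg$mean == 1))
  expect_true(all(agg$sem[agg$n == 2L] == 0))
  expect_true(all(agg$mean[agg$lag == 0L] == 1))

  ev2 <- list(list(intensity = c(1, 1.2), onset = 1L),
              list(intensity = c(1, 1.4), onset = 1L))
  agg2 <- pool_retraction_events(ev2)
  expect_equal(agg2$mean[agg2$lag == 1L], 1.3)

  ev3 <- list(list(intensity = c(0, 1, 2), onset = 1L),
              list(intensity = c(2, 2, 2), onset = 1L))
  expect_warning(agg3 <- pool_retraction_events(ev3), "zero intensity")
  expect_true(all(agg3$underpowered))
})
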
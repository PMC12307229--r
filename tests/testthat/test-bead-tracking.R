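# Bead detection filters, kymograph extraction and Otsu edge tracking.

test_that("a single static bead is detected at its true centroid", {
  ch <- make_bead_channel(centers = cbind(20, 20, 8))
  beads <- detect_beads(ch, edge_margin_px = 5)
  expect_equal(nrow(beads), 1L)
  expect_true(beads$accepted)
  expect_lt(abs(beads$y - 20), 0.5)
  expect_lt(abs(beads$x - 20), 0.5)
})

test_that("fused beads are rejected as aggregates and drifters as nonstationary", {
  fused <- make_bead_channel(centers = rbind(c(20, 18, 8), c(20, 22, 8)))
  b1 <- detect_beads(fused, max_area_px = 20, edge_margin_px = 5)
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$rejection_reason, "aggregate")

  drifting <- make_bead_channel(centers = cbind(20, 15, 8), drift = c(0, 5 / 7))
  b2 <- detect_beads(drifting, stationarity_max_shift_px = 2, edge_margin_px = 5)
  expect_equal(b2$rejection_reason, "nonstationary")

  edge <- make_bead_channel(centers = cbind(4, 20, 8))
  b3 <- detect_beads(edge, edge_margin_px = 6)
  expect_equal(b3$rejection_reason, "edge")
})

test_that("an all-zero bead channel yields an empty record set with a warning", {
  ch <- array(0, dim = c(3L, 4L, 10L, 10L))
  expect_warning(beads <- detect_beads(ch), "no beads")
  expect_equal(nrow(beads), 0L)
})

test_that("kymographs average the XY window per (z, t)", {
  ch <- array(7, dim = c(4L, 6L, 15L, 15L))
  bead <- data.frame(id = 1L, y = 8, x = 8, area_px = 9, accepted = TRUE,
                     rejection_reason = "none")
  kym <- extract_kymograph(ch, bead)
  expect_equal(dim(kym$values), c(6L, 4L))
  expect_true(all(kym$values == 7))

  kym0 <- extract_kymograph(ch, bead, xy_halfwidth_px = 0)
  expect_equal(dim(kym0$values), c(6L, 4L))

  near_edge <- data.frame(id = 2L, y = 2, x = 8, area_px = 9, accepted = TRUE,
                          rejection_reason = "none")
  expect_error(extract_kymograph(ch, near_edge), "bounds")
})

test_that("kymograph argmax matches the generator truth on noiseless beads", {
  p <- small_bead_params(n_beads = 2L,
                         noise_model = list(gaussian_sd = 0, poisson_on = FALSE))
  sc <- generate_bead_stack(p)
  beads <- detect_beads(sc$stack$channels$bead)
  expect_true(all(beads$accepted))
  for (i in seq_len(nrow(beads))) {
    j <- which.min((sc$truth$bead_xy_px[, "y"] - beads$y[i])^2 +
                     (sc$truth$bead_xy_px[, "x"] - beads$x[i])^2)
    kym <- extract_kymograph(sc$stack$channels$bead, beads[i, , drop = FALSE],
                             z_step_um = p$voxel_size_um[["z"]])
    z_arg <- (apply(kym$values, 2L, which.max) - 0.5) * kym$z_step_um
    expect_true(all(abs(z_arg - sc$truth$bead_z_um[j, ]) <= kym$z_step_um + 1e-9))
  }
})

test_that("edge tracking interpolates a mid-step edge to half a z-step", {
  # bead-like column: bright up to z = 10, dark beyond; constant over time
  prof <- c(rep(0, 3), rep(1, 7), rep(0, 10))
  kym <- make_kymograph(matrix(prof, 20L, 6L))
  tr <- track_edge(kym, smooth_z_sigma_steps = 0, median_filter_t = 1L)
  expect_true(all(tr$valid))
  expect_equal(tr$edge_z_um, rep(10.5 * 0.1, 6L), tolerance = 0.02)
  # displacement after the fallback baseline is exactly 0
  expect_equal(tr$displacement_um, rep(0, 6L))
})

test_that("static noiseless beads report near-zero displacement", {
  ch <- make_bead_channel(nT = 6L, centers = cbind(20, 20, 8))
  bead <- detect_beads(ch, edge_margin_px = 5)
  kym <- extract_kymograph(ch, bead)
  tr <- track_edge(kym)
  expect_true(all(abs(tr$displacement_um[tr$valid]) < 0.05))
})

test_that("frames whose profile never crosses the threshold are invalid", {
  v <- matrix(0, 12L, 5L)
  v[4:7, c(1L, 2L, 4L, 5L)] <- 10      # frame 3 stays dark
  v[1L, 3L] <- 1e-3
  kym <- make_kymograph(v)
  tr <- track_edge(kym, median_filter_t = 1L)
  expect_false(tr$valid[3L])
  expect_true(all(tr$valid[c(1L, 2L, 4L, 5L)]))
})

test_that("degenerate kymographs raise errors", {
  expect_error(track_edge(make_kymograph(matrix(5, 10L, 4L))), "dynamic range")
  expect_error(track_edge(make_kymograph(matrix(c(0, 1), 2L, 4L))), "Z >= 3")
})

test_that("edges are equivariant to z-translation and invariant to gain", {
  p <- small_bead_params(n_beads = 2L)
  sc <- generate_bead_stack(p)
  ch <- sc$stack$channels$bead
  beads <- detect_beads(ch)
  b <- beads[which(beads$accepted)[1L], , drop = FALSE]
  kym <- extract_kymograph(ch, b)
  tr <- track_edge(kym)

  kshift <- 4L
  kym_sh <- kym
  nZ <- nrow(kym$values)
  kym_sh$values <- rbind(matrix(0, kshift, ncol(kym$values)),
                         kym$values[seq_len(nZ - kshift), ])
  tr_sh <- track_edge(kym_sh)
  ok <- tr$valid & tr_sh$valid
  expect_equal(tr_sh$edge_z_um[ok], tr$edge_z_um[ok] + kshift * kym$z_step_um,
               tolerance = 1e-6)
  expect_equal(tr_sh$displacement_um[ok], tr$displacement_um[ok], tolerance = 1e-6)

  kym_g <- kym
  kym_g$values <- kym$values * 3.7
  tr_g <- track_edge(kym_g)
  expect_equal(tr_g$edge_z_um, tr$edge_z_um, tolerance = 1e-6)
})

test_that("edges agree with a brute-force half-maximum oracle on noiseless scenes", {
  p <- small_bead_params(n_beads = 2L,
                         noise_model = list(gaussian_sd = 0, poisson_on = FALSE))
  sc <- generate_bead_stack(p)
  ch <- sc$stack$channels$bead
  beads <- detect_beads(ch)
  for (i in which(beads$accepted)) {
    kym <- extract_kymograph(ch, beads[i, , drop = FALSE],
                             z_step_um = p$voxel_size_um[["z"]])
    tr <- track_edge(kym)
    half_max <- apply(kym$values, 2L, function(col) {
      thr <- max(col) / 2
      k <- max(which(col >= thr))
      if (k == length(col)) return(NA_real_)
      k + (col[k] - thr) / (col[k] - col[k + 1L])
    })
    ok <- tr$valid & is.finite(half_max)
    expect_true(all(abs(tr$edge_z_um[ok] / kym$z_step_um - half_max[ok]) <= 1))
  }
})

test_that("max_displacement follows its definition", {
  expect_equal(max_displacement(make_trace(c(0, 0.2, 0.8, 0.3))), 0.8)
  expect_equal(max_displacement(make_trace(rep(0, 5L))), 0)
  expect_error(max_displacement(make_trace(c(1, 2), valid = c(FALSE, FALSE))),
               "no valid frames")
})
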
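# Shared fixtures: compact synthetic scenes (kept small so the suite stays
# fast) and tiny hand-built stacks for detection edge cases.

small_bead_params <- function(...) {
  over <- list(...)
  base <- list(image_shape = c(t = 30L, z = 32L, y = 64L, x = 220L),
               n_beads = 4L, cell_speed_um_per_s = 0.075,
               noise_model = list(gaussian_sd = 5, poisson_on = FALSE),
               seed = 11L)
  do.call(bead_scene_params, utils::modifyList(base, over, keep.null = TRUE))
}

# bead channel with Gaussian beads at given (y, x, z-voxel) centers; optional
# per-frame xy drift (px/frame)
make_bead_channel <- function(nT = 8L, nZ = 16L, nY = 40L, nX = 40L,
                              centers, sigma_px = 1.5, sigma_z = 3,
                              peak = 100, drift = c(0, 0)) {
  arr <- array(0, dim = c(nT, nZ, nY, nX))
  for (t in seq_len(nT)) {
    for (i in seq_len(nrow(centers))) {
      cy <- centers[i, 1L] + drift[1L] * (t - 1L)
      cx <- centers[i, 2L] + drift[2L] * (t - 1L)
      cz <- centers[i, 3L]
      py <- exp(-((seq_len(nY) - cy)^2) / (2 * sigma_px^2))
      px <- exp(-((seq_len(nX) - cx)^2) / (2 * sigma_px^2))
      pz <- exp(-((seq_len(nZ) - cz)^2) / (2 * sigma_z^2))
      arr[t, , , ] <- arr[t, , , ] + peak * outer(pz, outer(py, px))
    }
  }
  arr
}

# channel_traces object straight from numeric vectors
make_traces <- function(actin, nucleus = rep(1, length(actin)), bead_id = 1L) {
  structure(list(actin = actin, nucleus = nucleus,
                 window_halfwidth_px = 10L, bead_id = bead_id),
            class = "channel_traces")
}

# displacement_trace object from an edge series (um)
make_trace <- function(edge_z_um, baseline_um = 0,
                       valid = rep(TRUE, length(edge_z_um))) {
  structure(list(edge_z_um = edge_z_um, baseline_um = baseline_um,
                 displacement_um = edge_z_um - baseline_um, valid = valid,
                 z_step_um = 0.1, frame_interval_s = 30, bead_id = 1L),
            class = "displacement_trace")
}

make_kymograph <- function(values, z_step_um = 0.1) {
  structure(list(values = values, z_step_um = z_step_um,
                 frame_interval_s = 30, bead_id = 1L),
            class = "kymograph")
}

# label matrices for a sequence of disc centers: list over frames; centers a
# list of n x 2 (y, x) matrices (one row per cell present in that frame)
disc_label_frames <- function(centers_per_frame, nY = 60L, nX = 60L, r = 6) {
  lapply(centers_per_frame, function(cen) {
    lab <- matrix(0L, nY, nX)
    if (is.null(cen)) return(lab)
    cen <- matrix(cen, ncol = 2L)
    for (i in seq_len(nrow(cen))) {
      d2 <- outer((seq_len(nY) - cen[i, 1L])^2, (seq_len(nX) - cen[i, 2L])^2, "+")
      lab[d2 <= r^2] <- i
    }
    lab
  })
}

# brute-force local maxima oracle: strict neighborhood max with the same
# tie rule (value desc, then lexicographic ascending, suppression > radius)
brute_local_maxima <- function(field, radius, min_prominence) {
  med <- stats::median(field)
  cand <- matrix(NA_integer_, 0L, 2L); vals <- numeric(0)
  off <- expand.grid(dy = -ceiling(radius):ceiling(radius),
                     dx = -ceiling(radius):ceiling(radius))
  off <- off[off$dy^2 + off$dx^2 <= radius^2 & !(off$dy == 0 & off$dx == 0), ]
  for (y in seq_len(nrow(field))) for (x in seq_len(ncol(field))) {
    if (field[y, x] <= med + min_prominence) next
    ny <- y + off$dy; nx <- x + off$dx
    ok <- ny >= 1 & ny <= nrow(field) & nx >= 1 & nx <= ncol(field)
    if (all(field[cbind(ny[ok], nx[ok])] <= field[y, x])) {
      cand <- rbind(cand, c(y, x)); vals <- c(vals, field[y, x])
    }
  }
  if (!nrow(cand)) return(cand)
  ord <- order(-vals, cand[, 1L], cand[, 2L])
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    kept <- cand[keep, , drop = FALSE]
    if (min((kept[, 1L] - cand[i, 1L])^2 + (kept[, 2L] - cand[i, 2L])^2) >
        radius^2) keep[i] <- TRUE
  }
  res <- cand[keep, , drop = FALSE]
  res[order(res[, 1L], res[, 2L]), , drop = FALSE]
}
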
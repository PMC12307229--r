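# Synthetic microscopy scene generators with exact ground truth.
#
# Every assay geometry the quantification stages consume can be emulated here:
# beads embedded in an elastic layer and pushed vertically by a passing cell,
# a migrating cell with coupled central-pool / lamellipodial actin dynamics,
# a constricted microchannel passage, and paired deformation/actin 2D fields.
# Scenes are deterministic for a fixed seed and carry a `ground_truth` record
# so that downstream measurements can be validated exactly.

#' Parameters of a synthetic bead-displacement scene
#'
#' Defaults mirror the acquisition geometry of the pushing-force assay:
#' confocal Z-stacks with 0.1 um step, frames every 30 s, ~1 um beads
#' (rendered as sub-resolution Gaussians), and a cell whose central actin
#' pool and trailing nucleus vertically displace any bead they pass under.
#'
#' @param image_shape named integer `c(t=, z=, y=, x=)` voxel counts.
#' @param voxel_size_um named numeric `c(z=, y=, x=)`, micrometers.
#' @param frame_interval_s frame spacing, seconds.
#' @param n_beads number of beads placed along the cell path.
#' @param bead_sigma_um isotropic Gaussian radius of a rendered bead.
#' @param bead_baseline_z_um resting bead depth above the coverslip.
#' @param displacement_amplitude_um peak vertical push (>= 0).
#' @param cell_speed_um_per_s centroid speed of the simulated cell.
#' @param cell_radius_um,central_pool_radius_um,nucleus_radius_um footprint radii.
#' @param intensity_levels named `c(background=, cytoplasm=, central_pool=, nucleus=)`
#'   photon-scale means; must be strictly increasing background -> central_pool.
#' @param bead_peak peak bead intensity above zero background.
#' @param ramp_frames frames of the raised-cosine rise/relaxation flanking the
#'   footprint-overlap plateau of the displacement envelope.
#' @param noise_model list with `gaussian_sd` and `poisson_on`.
#' @param seed integer RNG seed for the scene.
#' @return validated parameter list of class `bead_scene_params`.
#' @export
bead_scene_params <- function(image_shape = c(t = 40L, z = 32L, y = 96L, x = 360L),
                              voxel_size_um = c(z = 0.1, y = 0.16, x = 0.16),
                              frame_interval_s = 30,
                              n_beads = 20L,
                              bead_sigma_um = 0.4,
                              bead_baseline_z_um = 1.0,
                              displacement_amplitude_um = 0.8,
                              cell_speed_um_per_s = 0.06,
                              cell_radius_um = 8,
                              central_pool_radius_um = 2,
                              nucleus_radius_um = 2.5,
                              intensity_levels = c(background = 5, cytoplasm = 40,
                                                   central_pool = 150, nucleus = 120),
                              bead_peak = 100,
                              ramp_frames = 3L,
                              noise_model = list(gaussian_sd = 5, poisson_on = FALSE),
                              seed = 1L) {
  p <- list(image_shape = image_shape, voxel_size_um = voxel_size_um[c("z", "y", "x")],
            frame_interval_s = frame_interval_s, n_beads = as.integer(n_beads),
            bead_sigma_um = bead_sigma_um, bead_baseline_z_um = bead_baseline_z_um,
            displacement_amplitude_um = displacement_amplitude_um,
            cell_speed_um_per_s = cell_speed_um_per_s,
            cell_radius_um = cell_radius_um,
            central_pool_radius_um = central_pool_radius_um,
            nucleus_radius_um = nucleus_radius_um,
            intensity_levels = intensity_levels, bead_peak = bead_peak,
            ramp_frames = as.integer(ramp_frames),
            noise_model = noise_model, seed = as.integer(seed))
  stopifnot(all(p$image_shape >= 1), all(p$voxel_size_um > 0),
            p$frame_interval_s > 0, p$n_beads >= 1, p$bead_sigma_um > 0,
            p$bead_baseline_z_um > 0, p$displacement_amplitude_um >= 0,
            p$cell_speed_um_per_s >= 0, p$bead_peak > 0)
  lv <- p$intensity_levels[c("background", "cytoplasm", "central_pool")]
  if (any(diff(lv) <= 0)) {
    stop("intensity_levels must increase strictly from background to central_pool",
         call. = FALSE)
  }
  class(p) <- "bead_scene_params"
  p
}

# channel sub-stream seeds, kept well below 2^31
channel_seed <- function(seed, k) (abs(seed) %% 1000003L) * 1009L + k

add_noise <- function(arr, noise_model, seed) {
  gs <- noise_model$gaussian_sd %||% 0
  if (isTRUE(noise_model$poisson_on)) {
    arr[] <- withr::with_seed(seed, stats::rpois(length(arr), pmax(arr, 0)))
  }
  if (gs > 0) {
    arr <- arr + withr::with_seed(seed + 1L,
                                  stats::rnorm(length(arr), 0, gs))
  }
  arr
}

# raised-cosine displacement envelope over the footprint-overlap window
# [t0, t1]: rises over the `ramp` frames before t0 (the cell body already
# covers the bead there), holds 1 from t0, and relaxes *within* the window so
# that the substrate is back at baseline once the cell has passed — beads
# must never be displaced on frames with no cell under them.
raised_cosine_envelope <- function(n, t0, t1, ramp) {
  env <- numeric(n)
  if (is.na(t0)) return(env)
  # hold the plateau for at least 3 frames (shortening the relaxation if the
  # overlap window is short) so the tracked maximum is a sustained feature
  f0 <- max(t1 - ramp, min(t0 + 2L, t1))
  env[t0:f0] <- 1
  if (ramp > 0) {
    for (j in seq_len(ramp)) {
      u <- 0.5 * (1 - cos(pi * (ramp - j) / ramp))
      if (t0 - j >= 1) env[t0 - j] <- u
    }
    nf <- t1 - f0
    if (nf > 0) {
      for (j in seq_len(nf)) env[f0 + j] <- 0.5 * (1 + cos(pi * j / (nf + 1)))
    }
  }
  env
}

#' Generate a bead-displacement Z-stack scene
#'
#' Renders a 3-channel (`bead`, `actin`, `nucleus`) `T,Z,Y,X` stack in which a
#' cell footprint (cytoplasm disc, bright central actin pool, trailing
#' nucleus) sweeps across a corridor of stationary beads.  Each bead's true
#' vertical position follows `baseline + amplitude * envelope(t)`, the
#' envelope being a raised cosine that plateaus at exactly 1 while the pool
#' or nucleus footprint overlaps the bead's XY position, so the true maximum
#' displacement equals the amplitude exactly.
#'
#' @param params a [bead_scene_params()].
#' @return list with elements `stack` ([image_stack()]) and `truth`, a
#'   `ground_truth` list carrying per-bead XY positions (px), true Z series
#'   (um), true displacements, per-frame compartment labels
#'   (`none`/`cytoplasm`/`central_actin`/`nucleus`), the envelope, and the
#'   cell centroid path.
#' @export
generate_bead_stack <- function(params = bead_scene_params()) {
  stopifnot(inherits(params, "bead_scene_params"))
  d <- params$image_shape
  nT <- d[["t"]]; nZ <- d[["z"]]; nY <- d[["y"]]; nX <- d[["x"]]
  vz <- params$voxel_size_um[["z"]]
  vy <- params$voxel_size_um[["y"]]; vx <- params$voxel_size_um[["x"]]
  sig <- params$bead_sigma_um
  if (nZ * vz < params$bead_baseline_z_um + params$displacement_amplitude_um + 2 * sig ||
      nY * vy < 6 * sig || nX * vx < 6 * sig) {
    stop("image_shape too small to contain a bead footprint", call. = FALSE)
  }

  # cell path: fully off-field at both ends so every bead sees a 'none' epoch
  R <- params$cell_radius_um
  path_um <- params$cell_speed_um_per_s * params$frame_interval_s * (nT - 1)
  x_start <- -R - 1
  cx <- x_start + path_um * (seq_len(nT) - 1) / max(1, nT - 1)
  cy <- nY * vy / 2
  nuc_off <- params$central_pool_radius_um + params$nucleus_radius_um

  # bead corridor: passed over completely, clear of the image border
  margin_um <- max(2.0, 11 * vx)           # room for a 21 px analysis window
  corr_lo <- max(margin_um, x_start + R + 1)
  corr_hi <- min(nX * vx - margin_um, cx[nT] - R - nuc_off - 1)
  if (corr_hi - corr_lo < 1) {
    stop("scene too small/slow: the cell does not clear a bead corridor",
         call. = FALSE)
  }
  n <- params$n_beads
  slots <- corr_lo + (seq_len(n) - 0.5) / n * (corr_hi - corr_lo)
  jit_max <- max(0, min(0.3, (corr_hi - corr_lo) / n / 2 - 0.2))
  bead_xy_um <- withr::with_seed(params$seed, {
    bx <- slots + stats::runif(n, -jit_max, jit_max)
    by <- cy + stats::runif(n, -0.8, 0.8) * params$central_pool_radius_um
    cbind(x = bx, y = by)
  })

  # per-bead truth: overlap epochs, envelope, labels
  env <- matrix(0, n, nT)
  labels <- matrix("none", n, nT)
  for (i in seq_len(n)) {
    dx <- bead_xy_um[i, "x"] - cx
    dy <- bead_xy_um[i, "y"] - cy
    in_pool <- dx^2 + dy^2 <= params$central_pool_radius_um^2
    in_nuc <- (dx + nuc_off)^2 + dy^2 <= params$nucleus_radius_um^2
    in_cell <- dx^2 + dy^2 <= R^2
    labels[i, in_cell] <- "cytoplasm"
    labels[i, in_pool] <- "central_actin"
    labels[i, in_nuc] <- "nucleus"
    ov <- which(in_pool | in_nuc)
    if (length(ov)) {
      env[i, ] <- raised_cosine_envelope(nT, min(ov), max(ov), params$ramp_frames)
    }
  }
  bead_z_um <- params$bead_baseline_z_um + params$displacement_amplitude_um * env

  # render channels
  bead_ch <- array(0, dim = c(nT, nZ, nY, nX))
  actin_ch <- array(params$intensity_levels[["background"]], dim = dim(bead_ch))
  nuc_ch <- array(1, dim = dim(bead_ch))
  zc_um <- (seq_len(nZ) - 0.5) * vz
  yc_um <- (seq_len(nY) - 0.5) * vy
  xc_um <- (seq_len(nX) - 0.5) * vx
  hw_y <- ceiling(4 * sig / vy); hw_x <- ceiling(4 * sig / vx)
  n_cell_z <- max(1L, min(nZ, floor(0.8 / vz)))   # cell occupies the bottom ~0.8 um
  for (t in seq_len(nT)) {
    for (i in seq_len(n)) {
      iy <- round(bead_xy_um[i, "y"] / vy + 0.5)
      ix <- round(bead_xy_um[i, "x"] / vx + 0.5)
      ys <- max(1L, iy - hw_y):min(nY, iy + hw_y)
      xs <- max(1L, ix - hw_x):min(nX, ix + hw_x)
      pz <- exp(-(zc_um - bead_z_um[i, t])^2 / (2 * sig^2))
      py <- exp(-(yc_um[ys] - bead_xy_um[i, "y"])^2 / (2 * sig^2))
      px <- exp(-(xc_um[xs] - bead_xy_um[i, "x"])^2 / (2 * sig^2))
      bead_ch[t, , ys, xs] <- bead_ch[t, , ys, xs] +
        params$bead_peak * outer(pz, outer(py, px))
    }
    dy2 <- (yc_um - cy)^2
    dxc <- (xc_um - cx[t])^2
    cell <- outer(dy2, dxc, "+") <= R^2
    pool <- outer(dy2, dxc, "+") <= params$central_pool_radius_um^2
    nucd <- outer(dy2, (xc_um - (cx[t] - nuc_off))^2, "+") <=
      params$nucleus_radius_um^2
    lv <- params$intensity_levels
    af <- lv[["background"]] + (lv[["cytoplasm"]] - lv[["background"]]) * cell +
      (lv[["central_pool"]] - lv[["cytoplasm"]]) * pool
    nf <- 1 + lv[["nucleus"]] * nucd
    for (z in seq_len(n_cell_z)) {
      actin_ch[t, z, , ] <- af
      nuc_ch[t, z, , ] <- nf
    }
  }
  bead_ch <- add_noise(bead_ch, params$noise_model, channel_seed(params$seed, 1L))
  actin_ch <- add_noise(actin_ch, params$noise_model, channel_seed(params$seed, 3L))
  nuc_ch <- add_noise(nuc_ch, params$noise_model, channel_seed(params$seed, 5L))

  stack <- image_stack(list(bead = bead_ch, actin = actin_ch, nucleus = nuc_ch),
                       voxel_size_um = params$voxel_size_um,
                       frame_interval_s = params$frame_interval_s)
  truth <- structure(list(
    bead_xy_px = cbind(y = bead_xy_um[, "y"] / vy + 0.5,
                       x = bead_xy_um[, "x"] / vx + 0.5),
    bead_z_um = bead_z_um,
    displacement_um = bead_z_um - params$bead_baseline_z_um,
    baseline_z_um = params$bead_baseline_z_um,
    labels = labels,
    envelope = env,
    cell_centroid_px = cbind(y = rep(cy / vy + 0.5, nT), x = cx / vx + 0.5),
    params = params), class = "ground_truth")
  list(stack = stack, truth = truth)
}

#' Parameters of a synthetic 2D migration movie
#'
#' @param image_shape named integer `c(t=, y=, x=)`.
#' @param pixel_size_um,frame_interval_s calibrations.
#' @param cell_radius_um,central_pool_radius_um,nucleus_radius_um,
#'   lamellipodium_depth_um footprint geometry (the lamellipodium is the
#'   front rim band of the cell disc).
#' @param protrusion_extension_um how far the front outline extends (retracts)
#'   per unit of the protrusion latent — leading-edge actin accumulation and
#'   protrusion growth go together, so gained-area intensity reports the
#'   latent.
#' @param cell_speed_um_per_s centroid speed along +x.
#' @param intensity_levels named means as in [bead_scene_params()], plus the
#'   lamellipodial band level via `lamellipodium`.
#' @param fluctuation_amplitude relative amplitude of the latent intensity
#'   fluctuations of pool and lamellipodium.
#' @param smoothness_frames Gaussian correlation time of the latent series.
#' @param noise_model list with `gaussian_sd`, `poisson_on`.
#' @return validated list of class `migration_scene_params`.
#' @export
migration_scene_params <- function(image_shape = c(t = 80L, y = 120L, x = 220L),
                                   pixel_size_um = 0.32,
                                   frame_interval_s = 30,
                                   cell_radius_um = 8,
                                   central_pool_radius_um = 2.5,
                                   nucleus_radius_um = 3,
                                   lamellipodium_depth_um = 2,
                                   protrusion_extension_um = 1.5,
                                   cell_speed_um_per_s = 0.02,
                                   intensity_levels = c(background = 5,
                                                        cytoplasm = 50,
                                                        lamellipodium = 100,
                                                        central_pool = 150,
                                                        nucleus = 120),
                                   fluctuation_amplitude = 0.35,
                                   smoothness_frames = 2,
                                   noise_model = list(gaussian_sd = 2,
                                                      poisson_on = FALSE)) {
  p <- list(image_shape = image_shape, pixel_size_um = pixel_size_um,
            frame_interval_s = frame_interval_s, cell_radius_um = cell_radius_um,
            central_pool_radius_um = central_pool_radius_um,
            nucleus_radius_um = nucleus_radius_um,
            lamellipodium_depth_um = lamellipodium_depth_um,
            protrusion_extension_um = protrusion_extension_um,
            cell_speed_um_per_s = cell_speed_um_per_s,
            intensity_levels = intensity_levels,
            fluctuation_amplitude = fluctuation_amplitude,
            smoothness_frames = smoothness_frames, noise_model = noise_model)
  stopifnot(all(p$image_shape >= 1), p$pixel_size_um > 0, p$frame_interval_s > 0,
            p$cell_radius_um > 0, p$fluctuation_amplitude >= 0)
  class(p) <- "migration_scene_params"
  p
}

# smooth standardized latent series of length n (+pad on both sides)
latent_series <- function(n, pad, smoothness) {
  k <- gaussian_kernel_1d(smoothness)
  e <- stats::rnorm(n + 2L * pad)
  s <- smooth_vector(e, k)
  as.numeric(scale(s))
}

#' Generate a migrating-cell movie with coupled actin pools
#'
#' A 2-channel (`actin`, `nucleus`) `T,Y,X` movie of a disc-shaped cell with a
#' lamellipodial front band and a central actin pool.  The latent intensity
#' series of the two compartments are constructed so that the central series
#' equals `coupling_coefficient` times the protrusion series delayed by
#' `coupling_lag_frames` plus an independent smooth residual; a positive lag
#' means the central pool follows the protrusion.
#'
#' @param params a [migration_scene_params()].
#' @param coupling_coefficient in `[-1, 1]`.
#' @param coupling_lag_frames integer lag (frames).
#' @param seed integer RNG seed.
#' @return list with `stack` and `truth`; `truth` carries the latent series
#'   (`latent_protrusion`, `latent_central`), the true lag and sign, the
#'   centroid path, and per-frame logical masks (`cell`, `pool`,
#'   `lamellipodium`, `nucleus`).
#' @export
generate_migration_movie <- function(params = migration_scene_params(),
                                     coupling_coefficient = -0.8,
                                     coupling_lag_frames = 0L,
                                     seed = 1L) {
  stopifnot(inherits(params, "migration_scene_params"),
            abs(coupling_coefficient) <= 1)
  d <- params$image_shape
  nT <- d[["t"]]; nY <- d[["y"]]; nX <- d[["x"]]
  lag <- as.integer(coupling_lag_frames)
  if (nT < 4L * abs(lag) + 10L) {
    stop("degenerate scene: need T >= 4*|lag| + 10 frames", call. = FALSE)
  }
  px <- params$pixel_size_um
  pad <- abs(lag) + ceiling(4 * params$smoothness_frames) + 4L
  lat <- withr::with_seed(seed, {
    zp <- latent_series(nT, pad, params$smoothness_frames)
    zq <- latent_series(nT, pad, params$smoothness_frames)
    list(zp = zp, zq = zq)
  })
  idx <- pad + seq_len(nT)
  zp <- lat$zp[idx]
  zc <- coupling_coefficient * lat$zp[idx - lag] +
    sqrt(1 - coupling_coefficient^2) * lat$zq[idx]
  a <- params$fluctuation_amplitude
  f_band <- pmax(0.2, 1 + a * zp)
  f_pool <- pmax(0.2, 1 + a * zc)
  ext <- params$protrusion_extension_um * pmax(pmin(zp, 2), -2) / 2

  cyv <- nY * px / 2
  cxv <- params$cell_radius_um + params$protrusion_extension_um + 1 +
    params$cell_speed_um_per_s * params$frame_interval_s * (seq_len(nT) - 1)
  reach <- cxv[nT] + params$cell_radius_um + params$protrusion_extension_um
  if (reach > nX * px) {
    warning("generate_migration_movie: cell leaves the field near the end; ",
            "enlarge image_shape x or lower speed/T")
  }
  lv <- params$intensity_levels
  yc <- (seq_len(nY) - 0.5) * px
  xc <- (seq_len(nX) - 0.5) * px
  actin <- array(0, dim = c(nT, nY, nX))
  nucch <- array(0, dim = c(nT, nY, nX))
  masks <- list(cell = vector("list", nT), pool = vector("list", nT),
                lamellipodium = vector("list", nT), nucleus = vector("list", nT))
  nuc_off <- params$central_pool_radius_um + params$nucleus_radius_um - 1
  for (t in seq_len(nT)) {
    dy2 <- (yc - cyv)^2
    dx <- xc - cxv[t]
    r2 <- outer(dy2, dx^2, "+")
    front <- outer(rep(TRUE, nY), dx > 0)
    rfront <- params$cell_radius_um + ext[t]
    cell <- (r2 <= params$cell_radius_um^2 & !front) |
      (r2 <= rfront^2 & front)
    band <- front & cell &
      r2 >= (rfront - params$lamellipodium_depth_um)^2
    pool <- r2 <= params$central_pool_radius_um^2
    nucd <- outer(dy2, (xc - (cxv[t] - nuc_off))^2, "+") <=
      params$nucleus_radius_um^2
    af <- lv[["background"]] + (lv[["cytoplasm"]] - lv[["background"]]) * cell
    af <- af + (lv[["lamellipodium"]] * f_band[t] - lv[["cytoplasm"]]) * band
    af <- af + (lv[["central_pool"]] * f_pool[t] - lv[["cytoplasm"]]) * pool
    actin[t, , ] <- af
    nucch[t, , ] <- 1 + lv[["nucleus"]] * nucd
    masks$cell[[t]] <- cell; masks$pool[[t]] <- pool
    masks$lamellipodium[[t]] <- band; masks$nucleus[[t]] <- nucd
  }
  actin <- add_noise(actin, params$noise_model, channel_seed(seed, 11L))
  nucch <- add_noise(nucch, params$noise_model, channel_seed(seed, 13L))
  stack <- image_stack(list(actin = actin, nucleus = nucch),
                       voxel_size_um = c(z = 1, y = px, x = px),
                       frame_interval_s = params$frame_interval_s)
  truth <- structure(list(
    latent_protrusion = zp, latent_central = zc,
    coupling_lag_frames = lag, coupling_sign = sign(coupling_coefficient),
    coupling_coefficient = coupling_coefficient,
    pool_factor = f_pool, band_factor = f_band,
    cell_centroid_px = cbind(y = rep(cyv / px + 0.5, nT), x = cxv / px + 0.5),
    masks = masks, params = params), class = "ground_truth")
  list(stack = stack, truth = truth)
}

#' Parameters of a synthetic constricted-channel movie
#'
#' @param image_shape named integer `c(t=, y=, x=)`.
#' @param pixel_size_um,frame_interval_s calibrations (channel assays are
#'   imaged every 60 s).
#' @param channel_height_um,constriction_height_um lumen heights.
#' @param constriction_interval_px half-open, 0-based pixel column interval
#'   `c(x0, x1)` of the constriction.
#' @param plateau_intensity actin level of the cell outside the constriction.
#' @param cell_length_um length of the moving cell segment.
#' @param noise_model list with `gaussian_sd` (applied inside the lumen only,
#'   so masked-out pixels stay exactly at background).
#' @return validated list of class `constriction_scene_params`.
#' @export
constriction_scene_params <- function(image_shape = c(t = 30L, y = 60L, x = 200L),
                                      pixel_size_um = 0.32,
                                      frame_interval_s = 60,
                                      channel_height_um = 6,
                                      constriction_height_um = 1.7,
                                      constriction_interval_px = c(90L, 110L),
                                      plateau_intensity = 100,
                                      cell_length_um = 25,
                                      noise_model = list(gaussian_sd = 5,
                                                         poisson_on = FALSE)) {
  p <- list(image_shape = image_shape, pixel_size_um = pixel_size_um,
            frame_interval_s = frame_interval_s,
            channel_height_um = channel_height_um,
            constriction_height_um = constriction_height_um,
            constriction_interval_px = as.integer(constriction_interval_px),
            plateau_intensity = plateau_intensity,
            cell_length_um = cell_length_um, noise_model = noise_model)
  stopifnot(all(p$image_shape >= 1), p$pixel_size_um > 0,
            p$channel_height_um > 0,
            p$constriction_height_um <= p$channel_height_um,
            p$plateau_intensity > 0)
  ci <- p$constriction_interval_px
  if (ci[1L] < 0 || ci[2L] > p$image_shape[["x"]] || ci[1L] >= ci[2L]) {
    stop("constriction interval outside image", call. = FALSE)
  }
  class(p) <- "constriction_scene_params"
  p
}

#' Generate a constricted-channel passage movie
#'
#' Renders a cell segment translating through a microchannel lumen whose
#' actin signal inside the constriction interval is `enrichment_factor` times
#' the outside plateau.  Pixels outside the lumen mask are exactly background
#' (zero); noise is confined to the lumen.  A `brightfield` channel renders
#' the lumen for channel segmentation.
#'
#' @param params a [constriction_scene_params()].
#' @param enrichment_factor in-constriction enrichment (>= 0).
#' @param seed integer RNG seed.
#' @return list with `stack` (channels `actin`, `brightfield`), `channel_mask`
#'   (logical Y x X lumen mask), and `truth` (mask, constriction interval,
#'   enrichment factor, per-frame cell interval).
#' @export
generate_constriction_movie <- function(params = constriction_scene_params(),
                                        enrichment_factor = 3,
                                        seed = 1L) {
  stopifnot(inherits(params, "constriction_scene_params"), enrichment_factor >= 0)
  d <- params$image_shape
  nT <- d[["t"]]; nY <- d[["y"]]; nX <- d[["x"]]
  px <- params$pixel_size_um
  h <- max(1L, round(params$channel_height_um / px))
  hc <- max(1L, round(params$constriction_height_um / px))
  yc <- nY %/% 2L
  mask <- matrix(FALSE, nY, nX)
  rows_full <- (yc - h %/% 2L + 1L):(yc + (h - h %/% 2L))
  rows_con <- (yc - hc %/% 2L + 1L):(yc + (hc - hc %/% 2L))
  ci <- params$constriction_interval_px
  con_cols <- (ci[1L] + 1L):ci[2L]                 # 1-based inclusive
  mask[rows_full, ] <- TRUE
  mask[setdiff(rows_full, rows_con), con_cols] <- FALSE

  Lpx <- params$cell_length_um / px
  cx_px <- -Lpx / 2 + (nX + Lpx) * (seq_len(nT) - 1) / max(1, nT - 1)
  col_level <- rep(1, nX)
  col_level[con_cols] <- enrichment_factor
  actin <- array(0, dim = c(nT, nY, nX))
  for (t in seq_len(nT)) {
    cols <- which(abs(seq_len(nX) - 0.5 - cx_px[t]) <= Lpx / 2)
    if (!length(cols)) next
    fr <- matrix(0, nY, nX)
    fr[, cols] <- params$plateau_intensity *
      matrix(col_level[cols], nY, length(cols), byrow = TRUE)
    fr[!mask] <- 0
    actin[t, , ] <- fr
  }
  gs <- params$noise_model$gaussian_sd %||% 0
  if (gs > 0) {
    noise <- withr::with_seed(channel_seed(seed, 21L),
                              array(stats::rnorm(length(actin), 0, gs), dim = dim(actin)))
    noise_mask <- array(rep(mask, each = nT), dim = dim(actin))
    actin <- actin + noise * noise_mask
  }
  bf <- array(20, dim = c(nT, nY, nX))
  for (t in seq_len(nT)) bf[t, , ] <- 20 + 60 * mask
  bf <- add_noise(bf, list(gaussian_sd = min(2, gs)), channel_seed(seed, 23L))
  stack <- image_stack(list(actin = actin, brightfield = bf),
                       voxel_size_um = c(z = 1, y = px, x = px),
                       frame_interval_s = params$frame_interval_s)
  truth <- structure(list(channel_mask = mask,
                          constriction_interval_px = ci,
                          enrichment_factor = enrichment_factor,
                          cell_center_px = cx_px,
                          params = params), class = "ground_truth")
  list(stack = stack, channel_mask = mask, truth = truth)
}

#' Generate a paired deformation/actin field
#'
#' Two smooth 2D fields built from isolated Gaussian bumps: `n_maxima_a`
#' deformation maxima, and `n_maxima_b` actin maxima of which the first
#' `min(n_maxima_a, n_maxima_b)` are displaced copies of deformation maxima at
#' a fixed offset (axis-aligned, rounded to whole pixels so the true
#' separation is exact).
#'
#' @param n_maxima_a,n_maxima_b counts of deformation / actin maxima.
#' @param offset_um pairing offset, micrometers.
#' @param field_shape integer `c(y, x)` pixels.
#' @param pixel_size_um pixel size.
#' @param peak_sigma_px Gaussian bump radius in pixels.
#' @param noise_sd additive Gaussian noise (small relative to the bump
#'   amplitude of 100).
#' @param neighborhood_radius_px detection radius against which crowding is
#'   checked; if any two same-field maxima are closer, the truth carries
#'   `warn_close = TRUE`.
#' @param seed integer RNG seed.
#' @return list with `deformation`, `actin` (Y x X matrices) and `truth`
#'   (true maxima coordinates as `(y, x)` pixel matrices, achieved pair
#'   offset in um, crowding flag).
#' @export
generate_field_pair <- function(n_maxima_a, n_maxima_b, offset_um = 2,
                                field_shape = c(y = 80L, x = 80L),
                                pixel_size_um = 0.5, peak_sigma_px = 2,
                                noise_sd = 0.5, neighborhood_radius_px = 5,
                                seed = 1L) {
  stopifnot(n_maxima_a >= 1, n_maxima_b >= 0, offset_um >= 0)
  nY <- field_shape[[1L]]; nX <- field_shape[[2L]]
  off_px <- round(offset_um / pixel_size_um)
  m <- ceiling(4 * peak_sigma_px) + off_px + 2L
  if (2L * m >= min(nY, nX)) stop("field too small for the requested maxima",
                                  call. = FALSE)
  sep <- max(16, 8 * peak_sigma_px)
  place <- function(k, existing) {
    pts <- existing
    out <- matrix(NA_real_, 0L, 2L)
    tries <- 0L
    while (nrow(out) < k && tries < 4000L) {
      cand <- c(sample(m:(nY - m), 1L), sample(m:(nX - m), 1L))
      ok <- !nrow(pts) ||
        min((pts[, 1L] - cand[1L])^2 + (pts[, 2L] - cand[2L])^2) >= sep^2
      if (ok) {
        out <- rbind(out, cand)
        pts <- rbind(pts, cand)
      }
      tries <- tries + 1L
    }
    if (nrow(out) < k) stop("could not place maxima with the required separation",
                            call. = FALSE)
    out
  }
  res <- withr::with_seed(seed, {
    a <- place(n_maxima_a, matrix(NA_real_, 0L, 2L))
    npair <- min(n_maxima_a, n_maxima_b)
    b <- matrix(NA_real_, 0L, 2L)
    if (npair > 0L) {
      dirs <- matrix(c(0L, 1L, 0L, -1L, 1L, 0L, -1L, 0L), ncol = 2L, byrow = TRUE)
      mb <- m - off_px          # bump margin alone; a's margin already
      for (i in seq_len(npair)) {    # reserves room for the offset
        dd <- dirs[sample.int(4L, 1L), ] * off_px
        cand <- a[i, ] + dd
        cand <- pmin(pmax(cand, mb), c(nY - mb, nX - mb))
        b <- rbind(b, cand)
      }
    }
    if (n_maxima_b > npair) b <- rbind(b, place(n_maxima_b - npair, b))
    amp_a <- 100 * stats::runif(n_maxima_a, 0.9, 1.1)
    amp_b <- 100 * stats::runif(max(1L, n_maxima_b), 0.9, 1.1)
    na <- if (noise_sd > 0) matrix(stats::rnorm(nY * nX, 0, noise_sd), nY, nX) else 0
    nb <- if (noise_sd > 0) matrix(stats::rnorm(nY * nX, 0, noise_sd), nY, nX) else 0
    list(a = a, b = b, amp_a = amp_a, amp_b = amp_b, na = na, nb = nb)
  })
  render <- function(centers, amps) {
    f <- matrix(0, nY, nX)
    if (!nrow(centers)) return(f)
    ys <- seq_len(nY); xs <- seq_len(nX)
    for (i in seq_len(nrow(centers))) {
      f <- f + amps[i] * outer(exp(-(ys - centers[i, 1L])^2 / (2 * peak_sigma_px^2)),
                               exp(-(xs - centers[i, 2L])^2 / (2 * peak_sigma_px^2)))
    }
    f
  }
  def_field <- render(res$a, res$amp_a) + res$na
  act_field <- render(res$b, res$amp_b) + res$nb
  all_sep_ok <- function(p) {
    if (nrow(p) < 2L) return(TRUE)
    dm <- as.matrix(stats::dist(p))
    diag(dm) <- Inf
    min(dm) > neighborhood_radius_px
  }
  npair <- min(n_maxima_a, n_maxima_b)
  pair_off <- if (npair > 0L) {
    sqrt(rowSums((res$a[seq_len(npair), , drop = FALSE] -
                    res$b[seq_len(npair), , drop = FALSE])^2)) * pixel_size_um
  } else numeric(0)
  truth <- structure(list(
    deformation_maxima_px = res$a, actin_maxima_px = res$b,
    pair_offset_um = pair_off, pixel_size_um = pixel_size_um,
    warn_close = !(all_sep_ok(res$a) && all_sep_ok(res$b))),
    class = "ground_truth")
  list(deformation = def_field, actin = act_field, truth = truth)
}
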
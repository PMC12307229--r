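# Pushing-force microscopy: bead detection and vertical edge tracking.
#
# Beads embedded in the elastic layer are segmented on the max projection
# over Z and time, filtered for stationarity and size, and each accepted bead
# is reduced to a Z x T intensity kymograph whose Otsu-thresholded edge
# (distal to the coverslip) reports the vertical substrate deformation.

#' Detect stationary beads in a bead channel
#'
#' Segments beads on the Otsu-thresholded maximum-intensity projection over Z
#' and time, then applies the paper-style filters: components larger than
#' `max_area_px` are rejected as aggregates, smaller than `min_area_px` as
#' too small, components whose per-frame XY centroid (from per-frame Z-max
#' projections) deviates from its time mean by more than
#' `stationarity_max_shift_px` at any frame as nonstationary, and beads
#' closer than `edge_margin_px` to the image border as edge cases.
#'
#' @param bead_channel numeric `T,Z,Y,X` array (or `image_stack` channel).
#' @param min_area_px,max_area_px inclusive component-area bounds (pixels).
#' @param stationarity_max_shift_px maximum tolerated per-frame centroid shift.
#' @param edge_margin_px analysis half-width kept clear of the border
#'   (defaults to the 20x20 px intensity-trace window half-width).
#' @return data.frame with one row per component: `id`, `y`, `x` (centroid,
#'   pixel units, pixel centers at integer + 0.5), `area_px`, `accepted`,
#'   `rejection_reason` in `none|too_small|aggregate|nonstationary|edge`.
#' @export
detect_beads <- function(bead_channel, min_area_px = 4, max_area_px = 200,
                         stationarity_max_shift_px = 2, edge_margin_px = 10) {
  stopifnot(length(dim(bead_channel)) == 4L, min_area_px > 0, max_area_px > 0,
            stationarity_max_shift_px > 0)
  d <- dim(bead_channel)
  nT <- d[1L]; nY <- d[3L]; nX <- d[4L]
  proj_t <- max_project_z(bead_channel)        # T,Y,X
  proj <- proj_t[1L, , , drop = TRUE]
  dim(proj) <- c(nY, nX)
  if (nT > 1L) for (t in seq(2L, nT)) {
    sl <- proj_t[t, , , drop = TRUE]; dim(sl) <- c(nY, nX)
    proj <- pmax(proj, sl)
  }
  empty <- data.frame(id = integer(), y = numeric(), x = numeric(),
                      area_px = numeric(), accepted = logical(),
                      rejection_reason = character())
  if (diff(range(proj)) <= 0) {
    warning("detect_beads: bead channel has no dynamic range; no beads found")
    return(empty)
  }
  thr <- otsu_threshold(proj)
  lab <- EBImage::bwlabel(EBImage::Image(t(proj) > thr))  # EBImage is x,y major
  lab <- t(EBImage::imageData(lab))                       # back to y,x
  nlab <- max(lab)
  if (nlab == 0L) {
    warning("detect_beads: nothing above threshold; no beads found")
    return(empty)
  }
  out <- empty
  for (i in seq_len(nlab)) {
    pix <- which(lab == i, arr.ind = TRUE)
    area <- nrow(pix)
    cy <- mean(pix[, 1L]) ; cx <- mean(pix[, 2L])
    reason <- "none"
    if (area < min_area_px) {
      reason <- "too_small"
    } else if (area > max_area_px) {
      reason <- "aggregate"
    } else if (cy <= edge_margin_px || cx <= edge_margin_px ||
               cy > nY - edge_margin_px || cx > nX - edge_margin_px) {
      reason <- "edge"
    } else {
      # stationarity: intensity-weighted centroid per frame inside a dilated bbox
      h <- 3L
      ys <- max(1L, min(pix[, 1L]) - h):min(nY, max(pix[, 1L]) + h)
      xs <- max(1L, min(pix[, 2L]) - h):min(nX, max(pix[, 2L]) + h)
      cys <- numeric(nT); cxs <- numeric(nT); okf <- logical(nT)
      for (t in seq_len(nT)) {
        w <- proj_t[t, ys, xs]
        dim(w) <- c(length(ys), length(xs))
        w <- pmax(w - thr, 0)
        sw <- sum(w)
        if (sw > 0) {
          cys[t] <- sum(w * ys) / sw
          cxs[t] <- sum(w * matrix(xs, length(ys), length(xs), byrow = TRUE)) / sw
          okf[t] <- TRUE
        }
      }
      if (any(okf)) {
        dev <- sqrt((cys[okf] - mean(cys[okf]))^2 + (cxs[okf] - mean(cxs[okf]))^2)
        if (max(dev) > stationarity_max_shift_px) reason <- "nonstationary"
      }
    }
    out <- rbind(out, data.frame(id = i, y = cy, x = cx, area_px = area,
                                 accepted = reason == "none",
                                 rejection_reason = reason))
  }
  out
}

#' Extract the Z x T kymograph of one bead
#'
#' For each `(z, t)` the kymograph value is the mean intensity over the
#' `(2*halfwidth + 1)^2` XY window centered on the bead centroid (default
#' 5 x 5 px), spanning the whole Z-stack.  A window that would exceed the
#' image bounds is an error rather than a silent clip.
#'
#' @param bead_channel numeric `T,Z,Y,X` array.
#' @param bead single-row data.frame as returned by [detect_beads()]
#'   (accepted).
#' @param xy_halfwidth_px window half-width (2 -> 5x5).
#' @param z_step_um,frame_interval_s calibrations carried on the kymograph.
#' @return object of class `kymograph`: list with `values` (Z x T matrix),
#'   `z_step_um`, `frame_interval_s`, `bead_id`.
#' @export
extract_kymograph <- function(bead_channel, bead, xy_halfwidth_px = 2,
                              z_step_um = 0.1, frame_interval_s = 30) {
  stopifnot(length(dim(bead_channel)) == 4L, nrow(bead) == 1L)
  if (!isTRUE(bead$accepted)) stop("extract_kymograph: bead was not accepted",
                                   call. = FALSE)
  d <- dim(bead_channel)
  h <- as.integer(xy_halfwidth_px)
  iy <- round(bead$y); ix <- round(bead$x)
  if (iy - h < 1L || ix - h < 1L || iy + h > d[3L] || ix + h > d[4L]) {
    stop("extract_kymograph: analysis window exceeds image bounds", call. = FALSE)
  }
  ys <- (iy - h):(iy + h); xs <- (ix - h):(ix + h)
  win <- bead_channel[, , ys, xs, drop = FALSE]
  km <- apply(win, c(2L, 1L), mean)          # Z x T
  structure(list(values = km, z_step_um = z_step_um,
                 frame_interval_s = frame_interval_s,
                 bead_id = bead$id),
            class = "kymograph")
}

# threshold crossing on the far side (largest z): last z with f >= thr,
# linearly interpolated towards the first below-threshold sample after it.
far_edge_crossing <- function(profile, thr) {
  above <- profile >= thr
  if (!any(above)) return(NA_real_)
  k <- max(which(above))
  if (k == length(profile)) return(NA_real_)   # edge leaves the stack
  k + (profile[k] - thr) / (profile[k] - profile[k + 1L])
}

#' Track the bead edge through time
#'
#' Computes one global Otsu threshold on the whole kymograph and locates, per
#' frame, the Z position where the bead intensity profile crosses it on the
#' side away from the substrate (larger Z = deeper into the gel), with linear
#' sub-step interpolation between the bracketing samples.  Frames whose
#' profile never crosses the threshold are flagged invalid.  The kymograph is
#' lightly smoothed along Z (Gaussian, default 1 z-step) and the edge series
#' passed through a short temporal median filter; both suppress
#' threshold-crossing jitter well below the z-step without biasing a
#' displacement plateau of three or more frames.
#'
#' @param kym a [extract_kymograph()] result.
#' @param edge_side only `"away_from_substrate"` is implemented (the cell
#'   pushes beads away from the coverslip).
#' @param baseline_frames frames used for the fallback baseline when no
#'   compartment labels are available yet; default the first and last 3
#'   valid frames.  Use [set_trace_baseline()] to re-baseline from
#'   `none`-labeled frames.
#' @param smooth_z_sigma_steps Gaussian sigma (z-steps) of the axial
#'   pre-smoothing; 0 disables.
#' @param median_filter_t odd temporal median window (frames); 1 disables.
#' @return object of class `displacement_trace`: list with `edge_z_um`,
#'   `baseline_um`, `displacement_um`, `valid`, `z_step_um`,
#'   `frame_interval_s`, `bead_id`.
#' @export
track_edge <- function(kym, edge_side = "away_from_substrate",
                       baseline_frames = NULL, smooth_z_sigma_steps = 1,
                       median_filter_t = 3L) {
  stopifnot(inherits(kym, "kymograph"))
  edge_side <- match.arg(edge_side)
  v <- kym$values
  if (nrow(v) < 3L) stop("track_edge: kymograph needs Z >= 3", call. = FALSE)
  if (diff(range(v)) <= 0) {
    stop("track_edge: kymograph has zero dynamic range (degenerate threshold)",
         call. = FALSE)
  }
  thr <- otsu_threshold(v)
  if (smooth_z_sigma_steps > 0) {
    k <- gaussian_kernel_1d(smooth_z_sigma_steps)
    v <- apply(v, 2L, smooth_vector, kernel = k)
  }
  edge_steps <- apply(v, 2L, far_edge_crossing, thr = thr)
  valid <- is.finite(edge_steps)
  if (median_filter_t > 1L && sum(valid) >= 3L) {
    edge_steps[valid] <- running_median(edge_steps[valid], as.integer(median_filter_t))
  }
  edge_z <- edge_steps * kym$z_step_um
  nT <- length(edge_z)
  if (is.null(baseline_frames)) {
    vi <- which(valid)
    baseline_frames <- unique(c(utils::head(vi, 3L), utils::tail(vi, 3L)))
  }
  bl_frames <- intersect(baseline_frames, which(valid))
  baseline <- if (length(bl_frames)) mean(edge_z[bl_frames]) else NA_real_
  structure(list(edge_z_um = edge_z,
                 baseline_um = baseline,
                 displacement_um = edge_z - baseline,
                 valid = valid,
                 z_step_um = kym$z_step_um,
                 frame_interval_s = kym$frame_interval_s,
                 bead_id = kym$bead_id),
            class = "displacement_trace")
}

#' Re-baseline a displacement trace from labeled frames
#'
#' The baseline is the mean edge position over frames classified `none`
#' (no cell under the bead); displacements are recomputed against it.
#'
#' @param trace a [track_edge()] result.
#' @param labels character vector of per-frame compartment labels, or a
#'   `contribution_labels` object.
#' @return the updated `displacement_trace`.
#' @export
set_trace_baseline <- function(trace, labels) {
  stopifnot(inherits(trace, "displacement_trace"))
  if (inherits(labels, "contribution_labels")) labels <- labels$labels
  stopifnot(length(labels) == length(trace$edge_z_um))
  none <- which(labels == "none" & trace$valid)
  if (!length(none)) {
    stop("set_trace_baseline: no valid 'none' frames; supply an external baseline",
         call. = FALSE)
  }
  trace$baseline_um <- mean(trace$edge_z_um[none])
  trace$displacement_um <- trace$edge_z_um - trace$baseline_um
  trace
}

#' Maximum absolute bead displacement
#'
#' @param trace a [track_edge()] result (with a finite baseline).
#' @return maximum of `|displacement_um|` over valid frames, micrometers.
#' @export
max_displacement <- function(trace) {
  stopifnot(inherits(trace, "displacement_trace"))
  ok <- trace$valid & is.finite(trace$displacement_um)
  if (!any(ok)) stop("max_displacement: no valid frames", call. = FALSE)
  max(abs(trace$displacement_um[ok]))
}
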
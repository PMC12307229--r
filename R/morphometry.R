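# 2D morphometry of single migrating cells: threshold segmentation of cell /
# central-pool / nucleus masks, greedy nearest-centroid track linking with the
# strict >10-frame filter, center-of-mass speed, protrusion (gained/lost area)
# decomposition, background-corrected intensity ratios, MTOC-first orientation
# calls, and pooling of lamellipodium-retraction events.

mask_centroid <- function(mask) {
  pix <- which(mask, arr.ind = TRUE)
  c(y = mean(pix[, 1L]), x = mean(pix[, 2L]))
}

largest_component <- function(binary) {
  lab <- EBImage::bwlabel(EBImage::Image(t(binary)))
  lab <- t(EBImage::imageData(lab))
  if (max(lab) == 0L) return(binary & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

#' Segment a cell, its central actin pool and its nucleus
#'
#' Threshold-based stand-in for a trained pixel classifier: the cell mask is
#' the largest connected component of the Otsu-thresholded, Gaussian-smoothed
#' actin frame; the central pool is the largest connected component above a
#' second, higher threshold (Otsu of the in-cell intensities) that lies
#' entirely inside the cell eroded by a rim band, so it can touch neither the
#' cell boundary nor the lamellipodial rim; the nucleus mask is the largest
#' Otsu component of the nucleus frame.  Externally produced masks bypass
#' this operation entirely (pass them straight to the downstream functions).
#'
#' @param actin_frame,nucleus_frame numeric Y x X matrices (nucleus may be
#'   `NULL`).
#' @param smooth_sigma_px Gaussian pre-smoothing sigma.
#' @param rim_width_px width of the boundary/lamellipodium exclusion band for
#'   the pool.
#' @return list of logical Y x X masks `cell`, `pool`, `nucleus` (empty masks
#'   for a blank frame; never an exception).
#' @export
segment_cell <- function(actin_frame, nucleus_frame = NULL, smooth_sigma_px = 2,
                         rim_width_px = 3L) {
  stopifnot(is.matrix(actin_frame))
  empty <- matrix(FALSE, nrow(actin_frame), ncol(actin_frame))
  seg_one <- function(fr, sigma = smooth_sigma_px, log_scale = FALSE) {
    if (diff(range(fr)) <= 0) return(empty)
    sm <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(fr)),
                                              sigma = sigma)))
    # log scale for the actin frame: the cell occupies a small area fraction
    # with several intensity tiers, and a linear histogram lets the bright
    # organelle pixels hijack the Otsu split
    if (log_scale) sm <- log1p(sm - min(sm))
    largest_component(sm > otsu_threshold(sm))
  }
  cell <- seg_one(actin_frame, log_scale = TRUE)
  pool <- empty
  if (any(cell)) {
    vals <- actin_frame[cell]
    if (diff(range(vals)) > 0) {
      thr2 <- otsu_threshold(vals)
      core <- t(EBImage::imageData(EBImage::erode(
        EBImage::Image(t(cell)),
        EBImage::makeBrush(2L * as.integer(rim_width_px) + 1L, "disc")))) > 0
      cand <- (actin_frame > thr2) & cell
      lab <- EBImage::bwlabel(EBImage::Image(t(cand)))
      lab <- t(EBImage::imageData(lab))
      best <- 0L; best_size <- 0L
      for (i in seq_len(max(lab))) {
        inside <- lab == i
        if (all(core[inside])) {
          if (sum(inside) > best_size) { best <- i; best_size <- sum(inside) }
        }
      }
      if (best > 0L) pool <- lab == best
    }
  }
  # nuclei are compact blobs: lighter smoothing keeps their boundary sharp
  nuc <- if (is.null(nucleus_frame)) empty else
    seg_one(nucleus_frame, sigma = smooth_sigma_px / 2)
  list(cell = cell, pool = pool, nucleus = nuc)
}

# label pairs that touch (8-connectivity) in a label matrix
touching_labels <- function(lab) {
  pairs <- matrix(integer(), 0L, 2L)
  shifts <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  nY <- nrow(lab); nX <- ncol(lab)
  for (s in shifts) {
    ys <- seq_len(nY - abs(s[1L])); xs <- seq_len(nX - abs(s[2L]))
    a <- lab[ys + max(0L, s[1L]), xs + max(0L, s[2L]), drop = FALSE]
    b <- lab[ys + max(0L, -s[1L]), xs + max(0L, -s[2L]), drop = FALSE]
    hit <- a > 0L & b > 0L & a != b
    if (any(hit)) pairs <- rbind(pairs, unique(cbind(a[hit], b[hit])))
  }
  unique(pairs)
}

#' Link per-frame cell masks into tracks
#'
#' Greedy nearest-centroid linking with a maximum step gate.  Masks that
#' touch another mask in a frame (interaction), or that are the nearest
#' candidate of two different track heads (a merge), terminate the tracks
#' involved and are excluded from assignment in that frame.  Tracks of length
#' `<= min_track_frames` (strictly longer survives) are discarded.
#'
#' @param label_frames list over frames of integer label matrices (0 =
#'   background; each positive label one cell mask).
#' @param max_step_px linking gate, pixels per frame.
#' @param min_track_frames strict lower bound on surviving track length
#'   (default 10: a 10-frame track is discarded, an 11-frame track kept).
#' @param pixel_size_um,frame_interval_s calibrations attached to each track.
#' @return list of `cell_track` objects: each a list with `frames` (integer
#'   time indices), `centroid_px` (n x 2, y/x), `area_px` (pixel counts),
#'   `labels` (mask label per frame), `pixel_size_um`, `frame_interval_s`.
#' @export
link_tracks <- function(label_frames, max_step_px = 20,
                        min_track_frames = 10L,
                        pixel_size_um = 0.32, frame_interval_s = 30) {
  stopifnot(length(label_frames) >= 1L)
  open <- list()    # each: list(frames, centroid, area, labels)
  done <- list()
  for (t in seq_along(label_frames)) {
    lab <- label_frames[[t]]
    ids <- setdiff(sort(unique(as.integer(lab))), 0L)
    touching <- touching_labels(lab)
    interacting <- unique(as.integer(touching))
    usable <- setdiff(ids, interacting)
    cent <- lapply(ids, function(i) mask_centroid(lab == i))
    names(cent) <- as.character(ids)
    areas <- vapply(ids, function(i) sum(lab == i), numeric(1))
    names(areas) <- as.character(ids)

    # nearest usable mask per open track
    nearest <- rep(NA_integer_, length(open))
    ndist <- rep(Inf, length(open))
    for (j in seq_along(open)) {
      tr <- open[[j]]
      last <- tr$centroid_px[nrow(tr$centroid_px), ]
      for (i in usable) {
        dd <- sqrt(sum((cent[[as.character(i)]] - last)^2))
        if (dd < ndist[j]) { ndist[j] <- dd; nearest[j] <- i }
      }
      if (is.finite(ndist[j]) && ndist[j] > max_step_px) {
        nearest[j] <- NA_integer_; ndist[j] <- Inf
      }
    }
    # merges: one mask claimed as nearest by several tracks terminates them
    nn <- nearest[!is.na(nearest)]
    contested <- unique(nn[duplicated(nn)])
    keep_open <- logical(length(open))
    assigned <- integer(0)
    for (j in seq_along(open)) {
      i <- nearest[j]
      if (!is.na(i) && !(i %in% contested) && !(i %in% assigned)) {
        key <- as.character(i)
        open[[j]]$frames <- c(open[[j]]$frames, t)
        open[[j]]$centroid_px <- rbind(open[[j]]$centroid_px, cent[[key]])
        open[[j]]$area_px <- c(open[[j]]$area_px, areas[[key]])
        open[[j]]$labels <- c(open[[j]]$labels, i)
        assigned <- c(assigned, i)
        keep_open[j] <- TRUE
      }
    }
    done <- c(done, open[!keep_open])
    open <- open[keep_open]
    # new tracks from unassigned, non-interacting, non-contested masks
    for (i in setdiff(usable, c(assigned, contested))) {
      key <- as.character(i)
      open <- c(open, list(list(frames = t,
                                centroid_px = matrix(cent[[key]], 1L, 2L,
                                                     dimnames = list(NULL, c("y", "x"))),
                                area_px = areas[[key]], labels = i)))
    }
  }
  done <- c(done, open)
  done <- Filter(function(tr) length(tr$frames) > min_track_frames, done)
  lapply(done, function(tr) {
    tr$pixel_size_um <- pixel_size_um
    tr$frame_interval_s <- frame_interval_s
    rownames(tr$centroid_px) <- NULL
    class(tr) <- "cell_track"
    tr
  })
}

#' Center-of-mass cell speed
#'
#' @param track a `cell_track` from [link_tracks()] (length >= 2).
#' @return list with `speed_um_per_min` (per-step series) and
#'   `mean_um_per_min`.
#' @export
cell_speed <- function(track) {
  stopifnot(inherits(track, "cell_track"))
  n <- nrow(track$centroid_px)
  if (n < 2L) stop("cell_speed: track too short", call. = FALSE)
  steps <- sqrt(rowSums(diff(track$centroid_px)^2)) * track$pixel_size_um
  per_min <- steps / (track$frame_interval_s / 60)
  list(speed_um_per_min = per_min, mean_um_per_min = mean(per_min))
}

#' Protrusion decomposition between consecutive masks
#'
#' The gained region is in the later mask but not the earlier one (new
#' protrusion), the lost region the reverse (retraction); by construction the
#' area difference between the masks equals gained minus lost exactly.
#'
#' @param mask_t,mask_t1 logical Y x X masks at times t and t+1.
#' @param pixel_size_um pixel size for areas.
#' @return list with `gained_mask`, `lost_mask`, `gained_area_um2`,
#'   `lost_area_um2`.
#' @export
protrusion_regions <- function(mask_t, mask_t1, pixel_size_um = 1) {
  stopifnot(identical(dim(mask_t), dim(mask_t1)))
  gained <- mask_t1 & !mask_t
  lost <- mask_t & !mask_t1
  list(gained_mask = gained, lost_mask = lost,
       gained_area_um2 = sum(gained) * pixel_size_um^2,
       lost_area_um2 = sum(lost) * pixel_size_um^2)
}

#' Background-corrected integrated intensity in a mask
#'
#' @param frame numeric Y x X matrix.
#' @param mask logical mask (non-empty).
#' @param background_estimate per-pixel background level; default the median
#'   intensity outside the mask.
#' @return `sum(frame[mask]) - background * sum(mask)`, clipped at 0 with a
#'   warning if negative.
#' @export
integrated_intensity <- function(frame, mask, background_estimate = NULL) {
  stopifnot(identical(dim(frame), dim(mask)))
  if (!any(mask)) stop("integrated_intensity: empty mask", call. = FALSE)
  if (is.null(background_estimate)) {
    background_estimate <- stats::median(frame[!mask])
  }
  val <- sum(frame[mask]) - background_estimate * sum(mask)
  if (val < 0) {
    warning("integrated_intensity: negative corrected intensity clipped to 0")
    val <- 0
  }
  val
}

#' Central-pool intensity normalized to the cell's time-integrated signal
#'
#' Per frame, the mean background-corrected intensity per pixel inside the
#' central pool divided by the cell's per-pixel mean corrected intensity
#' integrated over the whole track (total corrected intensity over total
#' masked area).  Dimensionless, invariant to camera gain and uniform offset.
#'
#' @param actin_frames list over frames of Y x X matrices.
#' @param cell_masks,pool_masks lists of logical masks (pool may be empty in
#'   some frames; at least one frame must have a pool).
#' @param background_estimate shared per-pixel background; default median
#'   outside the union of cell masks, per frame.
#' @return list with `per_frame` (ratio or NA where no pool) and `track_mean`.
#' @export
normalized_central_intensity <- function(actin_frames, cell_masks, pool_masks,
                                         background_estimate = NULL) {
  nT <- length(actin_frames)
  stopifnot(length(cell_masks) == nT, length(pool_masks) == nT)
  if (!any(vapply(pool_masks, any, logical(1)))) {
    stop("normalized_central_intensity: no central pool mask in any frame",
         call. = FALSE)
  }
  bg <- function(t) {
    if (!is.null(background_estimate)) background_estimate else
      stats::median(actin_frames[[t]][!cell_masks[[t]]])
  }
  tot_int <- 0; tot_area <- 0
  for (t in seq_len(nT)) {
    if (!any(cell_masks[[t]])) next
    tot_int <- tot_int + integrated_intensity(actin_frames[[t]], cell_masks[[t]], bg(t))
    tot_area <- tot_area + sum(cell_masks[[t]])
  }
  if (tot_int <= 0) stop("normalized_central_intensity: zero global intensity",
                         call. = FALSE)
  denom <- tot_int / tot_area
  per_frame <- vapply(seq_len(nT), function(t) {
    pm <- pool_masks[[t]]
    if (!any(pm)) return(NA_real_)
    integrated_intensity(actin_frames[[t]], pm, bg(t)) / sum(pm) / denom
  }, numeric(1))
  list(per_frame = per_frame, track_mean = mean(per_frame, na.rm = TRUE))
}

#' Lamellipodial F-actin density fraction
#'
#' Background-corrected intensity per unit area in the lamellipodium mask
#' divided by the same density over the whole cell mask.
#'
#' @param frame numeric Y x X matrix.
#' @param lamellipodium_mask,cell_mask logical masks, lamellipodium inside
#'   the cell, both non-empty.
#' @param background_estimate per-pixel background; default median outside
#'   the cell mask.
#' @return dimensionless density ratio.
#' @export
lamellipodium_fraction <- function(frame, lamellipodium_mask, cell_mask,
                                   background_estimate = NULL) {
  stopifnot(identical(dim(frame), dim(cell_mask)))
  if (!any(lamellipodium_mask) || !any(cell_mask)) {
    stop("lamellipodium_fraction: empty mask", call. = FALSE)
  }
  if (any(lamellipodium_mask & !cell_mask)) {
    stop("lamellipodium_fraction: lamellipodium mask outside the cell mask",
         call. = FALSE)
  }
  if (is.null(background_estimate)) {
    background_estimate <- stats::median(frame[!cell_mask])
  }
  dens <- function(m) integrated_intensity(frame, m, background_estimate) / sum(m)
  dens(lamellipodium_mask) / dens(cell_mask)
}

#' Default lamellipodium mask from the protrusion band
#'
#' The gained-region band between consecutive masks, dilated by 1 px and
#' intersected with the later cell mask — the automated stand-in for a
#' manually annotated lamellipodial region.
#'
#' @param mask_t,mask_t1 logical masks at t and t+1.
#' @return logical mask.
#' @export
lamellipodium_mask_default <- function(mask_t, mask_t1) {
  gained <- mask_t1 & !mask_t
  if (!any(gained)) return(gained)
  dil <- t(EBImage::imageData(EBImage::dilate(EBImage::Image(t(gained)),
                                              EBImage::makeBrush(3L, "box")))) > 0
  dil & mask_t1
}

#' Leading-edge rim band of a cell mask
#'
#' The front portion of the cell's boundary rim: the mask minus its erosion
#' by `depth_px`, restricted to the half-plane ahead of the centroid along
#' the motion direction.  This is the automated protrusion-actin region used
#' by the coupling pipeline (lamellipodial actin lives in this band).
#'
#' @param cell_mask logical Y x X mask.
#' @param direction `(y, x)` motion direction (need not be normalized).
#' @param depth_px rim depth in pixels.
#' @return logical mask (empty when the cell mask is empty).
#' @export
leading_edge_mask <- function(cell_mask, direction = c(0, 1), depth_px = 6L) {
  if (!any(cell_mask)) return(cell_mask)
  nv <- sqrt(sum(direction^2))
  if (!is.finite(nv) || nv == 0) direction <- c(0, 1) else
    direction <- direction / nv
  er <- t(EBImage::imageData(EBImage::erode(
    EBImage::Image(t(cell_mask)),
    EBImage::makeBrush(2L * as.integer(depth_px) + 1L, "disc")))) > 0
  rim <- cell_mask & !er
  cen <- mask_centroid(cell_mask)
  proj <- (row(cell_mask) - cen[["y"]]) * direction[1L] +
    (col(cell_mask) - cen[["x"]]) * direction[2L]
  rim & (proj > 0)
}

#' Classify MTOC-first vs nucleus-first orientation
#'
#' Projects the MTOC position relative to the nucleus centroid onto the
#' polarization axis; a positive projection (beyond a one-pixel tie zone)
#' means the MTOC leads.
#'
#' @param mtoc_px,nucleus_centroid_px numeric `(y, x)` positions in pixels.
#' @param axis_vector nonzero `(y, x)` polarization axis (e.g. the velocity
#'   direction over a +/-2-frame window for live tracks; fixed samples must
#'   supply one).
#' @param pixel_size_um pixel size.
#' @param tie_eps_px tie half-width in pixel-equivalents (default 1).
#' @return list with `value` (`"mtoc_first"`/`"nucleus_first"`),
#'   `projection_um`, `axis_unit`, `tie` flag.
#' @export
classify_orientation <- function(mtoc_px, nucleus_centroid_px, axis_vector,
                                 pixel_size_um = 1, tie_eps_px = 1) {
  stopifnot(all(is.finite(mtoc_px)), all(is.finite(nucleus_centroid_px)))
  nv <- sqrt(sum(axis_vector^2))
  if (!is.finite(nv) || nv == 0) stop("classify_orientation: zero axis vector",
                                      call. = FALSE)
  u <- axis_vector / nv
  proj_px <- sum((mtoc_px - nucleus_centroid_px) * u)
  tie <- abs(proj_px) < tie_eps_px
  list(value = if (!tie && proj_px > 0) "mtoc_first" else "nucleus_first",
       projection_um = proj_px * pixel_size_um,
       axis_unit = u, tie = tie)
}

#' Polarization axis from the centroid velocity
#'
#' @param track a `cell_track`.
#' @param frame index into the track.
#' @param halfwidth window half-width in frames (default 2).
#' @return `(y, x)` displacement vector over the window (not normalized).
#' @export
orientation_axis <- function(track, frame, halfwidth = 2L) {
  stopifnot(inherits(track, "cell_track"))
  n <- nrow(track$centroid_px)
  i0 <- max(1L, frame - halfwidth); i1 <- min(n, frame + halfwidth)
  if (i1 <= i0) stop("orientation_axis: track too short around frame", call. = FALSE)
  track$centroid_px[i1, ] - track$centroid_px[i0, ]
}

#' Pool lamellipodium-retraction events
#'
#' Each event carries per-region intensity series and an onset frame; series
#' are normalized to their own value at onset (so every region starts at 1),
#' aligned so that lag 0 is the onset, and averaged pointwise across events.
#' Events with zero intensity at onset are excluded with a warning; lags
#' covered by fewer than two events are flagged.
#'
#' @param events list; each element a list with `intensity` (numeric vector,
#'   or a matrix with one row per region and rownames) and `onset` (1-based
#'   column index).
#' @return data.frame with `region`, `lag`, `mean`, `sem`, `n`,
#'   `underpowered` (n < 2).
#' @export
pool_retraction_events <- function(events) {
  stopifnot(length(events) >= 1L)
  rows <- list()
  for (e in seq_along(events)) {
    ev <- events[[e]]
    m <- ev$intensity
    if (is.null(dim(m))) m <- matrix(m, 1L, dimnames = list("region", NULL))
    stopifnot(ev$onset >= 1L, ev$onset <= ncol(m))
    at0 <- m[, ev$onset]
    if (any(at0 == 0)) {
      warning("pool_retraction_events: event ", e,
              " has zero intensity at onset; excluded")
      next
    }
    norm <- m / at0
    lags <- seq_len(ncol(m)) - ev$onset
    for (rg in rownames(norm)) {
      rows[[length(rows) + 1L]] <-
        data.frame(region = rg, lag = lags, value = norm[rg, ])
    }
  }
  if (!length(rows)) stop("pool_retraction_events: no usable events", call. = FALSE)
  long <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(long, list(long$region, long$lag), drop = TRUE),
                               function(g) {
    data.frame(region = g$region[1L], lag = g$lag[1L], mean = mean(g$value),
               sem = sem(g$value), n = nrow(g), underpowered = nrow(g) < 2L)
  }))
  agg <- agg[order(agg$region, agg$lag), ]
  rownames(agg) <- NULL
  agg
}
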
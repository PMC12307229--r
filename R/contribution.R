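# Classification of which cell compartment lies under each bead per frame
# (none / cytoplasm / central actin pool / nucleus), from windowed actin and
# nucleus intensity traces, and per-region displacement summaries.

#' Extract actin and nucleus intensity traces around a bead
#'
#' Per frame, the total (summed) channel intensity over the full Z extent and
#' a `(2*halfwidth + 1)^2` XY window centered on the bead (default 21 x 21,
#' the 20 x 20 px volume of the assay rounded to an odd, centered window).
#'
#' @param actin_ch,nucleus_ch numeric `T,Z,Y,X` arrays.
#' @param bead single accepted row from [detect_beads()].
#' @param halfwidth_px window half-width (default 10).
#' @return object of class `channel_traces`: list with `actin`, `nucleus`
#'   (length-T non-negative series), `window_halfwidth_px`, `bead_id`.
#' @export
extract_channel_traces <- function(actin_ch, nucleus_ch, bead, halfwidth_px = 10) {
  stopifnot(length(dim(actin_ch)) == 4L, identical(dim(actin_ch), dim(nucleus_ch)),
            nrow(bead) == 1L)
  if (!isTRUE(bead$accepted)) stop("extract_channel_traces: bead was not accepted",
                                   call. = FALSE)
  d <- dim(actin_ch)
  h <- as.integer(halfwidth_px)
  iy <- round(bead$y); ix <- round(bead$x)
  if (iy - h < 1L || ix - h < 1L || iy + h > d[3L] || ix + h > d[4L]) {
    stop("extract_channel_traces: window exceeds image bounds", call. = FALSE)
  }
  ys <- (iy - h):(iy + h); xs <- (ix - h):(ix + h)
  sum_tr <- function(ch) {
    apply(ch[, , ys, xs, drop = FALSE], 1L, sum)
  }
  structure(list(actin = sum_tr(actin_ch), nucleus = sum_tr(nucleus_ch),
                 window_halfwidth_px = h, bead_id = bead$id),
            class = "channel_traces")
}

# 1D k-means with fixed seed and multiple restarts; returns cluster index per
# point, ordered so that cluster 1 has the lowest mean.
kmeans_1d <- function(x, k, seed, nstart = 10L) {
  if (length(unique(x)) < k) {
    stop("degenerate clustering: fewer distinct values than clusters", call. = FALSE)
  }
  km <- withr::with_seed(seed, stats::kmeans(x, centers = k, nstart = nstart))
  ord <- order(km$centers)
  rank <- match(seq_len(k), ord)
  list(cluster = rank[km$cluster], means = sort(as.numeric(km$centers)))
}

# frame-to-frame noise scale of a trace, robust to plateau structure:
# successive differences cancel slow structure, MAD ignores the few
# transition jumps, and /sqrt(2) undoes the difference-variance doubling.
trace_noise_scale <- function(x) {
  if (length(x) < 3L) return(stats::sd(x))
  stats::mad(diff(x)) / sqrt(2)
}

# suppress single-frame label flicker: runs of length 1 adopt the previous
# run's label (the first run adopts the following one).
enforce_min_dwell <- function(labels, min_dwell = 2L) {
  if (min_dwell <= 1L || length(labels) < 3L) return(labels)
  repeat {
    r <- rle(labels)
    if (length(r$lengths) < 2L || all(r$lengths >= min_dwell)) break
    i <- which(r$lengths < min_dwell)[1L]
    r$values[i] <- if (i > 1L) r$values[i - 1L] else r$values[i + 1L]
    labels <- inverse.rle(r)
  }
  labels
}

#' Classify per-frame compartment contributions from intensity traces
#'
#' One-dimensional K-means on the per-frame actin intensities of one bead,
#' with `k = 3` (none / cytoplasm / central actin, mapped by ascending
#' cluster mean) or `k = 2` (none / cytoplasm, for cells lacking a central
#' pool).  Frames whose nucleus intensity falls in the upper of a two-cluster
#' split of the nucleus trace are relabeled `nucleus`, overriding the actin
#' label; the override only fires when the two nucleus clusters are genuinely
#' separated (gap > 3x the larger within-cluster sd), so a flat or noise-only
#' nucleus trace never labels frames nucleus.  K-means uses a fixed seed and
#' at least 10 restarts; single-frame label flickers are absorbed into the
#' neighboring run (minimum dwell 2 frames).
#'
#' @param traces a [extract_channel_traces()] result.
#' @param k 2 or 3 actin clusters.
#' @param min_separation separation multiple (cluster-mean gap over the
#'   trace's frame-to-frame noise scale, estimated as the MAD of successive
#'   differences) required both to keep adjacent actin clusters distinct —
#'   unseparated clusters collapse into the lower class, so a no-cell noise
#'   trace yields all-`none` labels instead of arbitrary splits — and to
#'   apply the nucleus override.
#' @param seed RNG seed for the K-means restarts.
#' @param min_dwell_frames minimum run length enforced on the labels.
#' @return object of class `contribution_labels`: list with `labels`
#'   (length-T character in none/cytoplasm/central_actin/nucleus), `k_used`,
#'   `cluster_means` (ascending actin cluster means).
#' @export
classify_frames <- function(traces, k = 3L, min_separation = 3,
                            seed = 1L, min_dwell_frames = 2L) {
  stopifnot(inherits(traces, "channel_traces"), k %in% c(2L, 3L))
  x <- traces$actin
  if (length(x) < k) stop("classify_frames: need at least k frames", call. = FALSE)
  cl <- kmeans_1d(x, k, seed = seed)
  lab_map <- if (k == 3L) c("none", "cytoplasm", "central_actin") else
    c("none", "cytoplasm")
  # collapse adjacent clusters whose gap is not resolvable above the
  # frame-to-frame noise of the trace
  noise_x <- trace_noise_scale(x)
  cluster <- cl$cluster
  assign_to <- seq_len(k)
  for (j in seq(2L, k)) {
    lo <- x[assign_to[cluster] == assign_to[j - 1L]]
    hi <- x[cluster == j]
    gap <- mean(hi) - mean(lo)
    if (gap <= min_separation * max(noise_x, 1e-12)) {
      assign_to[j] <- assign_to[j - 1L]
    }
  }
  cluster <- assign_to[cluster]
  labels <- lab_map[cluster]
  # nucleus override from a guarded two-cluster split of the nucleus trace
  nx <- traces$nucleus
  if (length(unique(nx)) >= 2L) {
    ncl <- kmeans_1d(nx, 2L, seed = seed + 1L)
    hi <- ncl$cluster == 2L
    gap <- ncl$means[2L] - ncl$means[1L]
    if (gap > min_separation * max(trace_noise_scale(nx), 1e-12)) {
      labels[hi] <- "nucleus"
    }
  }
  labels <- enforce_min_dwell(labels, min_dwell_frames)
  structure(list(labels = labels, k_used = as.integer(k),
                 cluster_means = cl$means, bead_id = traces$bead_id),
            class = "contribution_labels")
}

#' Summarize displacement by compartment
#'
#' For each compartment present in the labels, the mean edge position over
#' its valid frames minus the baseline, where the baseline is the mean edge
#' over `none`-labeled frames (so the `none` region is 0 by construction).
#' Regions with no frames are absent from the output, not zero.
#'
#' @param trace a [track_edge()] result.
#' @param labels a [classify_frames()] result (or character vector).
#' @param baseline_um optional external baseline; required when no `none`
#'   frames exist.
#' @return data.frame with `region`, `mean_displacement_um`, `n_frames`.
#' @export
summarize_region_displacement <- function(trace, labels, baseline_um = NULL) {
  stopifnot(inherits(trace, "displacement_trace"))
  if (inherits(labels, "contribution_labels")) labels <- labels$labels
  stopifnot(length(labels) == length(trace$edge_z_um))
  none <- which(labels == "none" & trace$valid)
  if (is.null(baseline_um)) {
    if (!length(none)) {
      stop("summarize_region_displacement: no 'none' frames define a baseline; ",
           "supply baseline_um", call. = FALSE)
    }
    baseline_um <- mean(trace$edge_z_um[none])
  }
  regions <- intersect(c("none", "cytoplasm", "central_actin", "nucleus"),
                       unique(labels))
  rows <- lapply(regions, function(rg) {
    idx <- which(labels == rg & trace$valid)
    if (!length(idx)) return(NULL)
    data.frame(region = rg,
               mean_displacement_um = mean(trace$edge_z_um[idx]) - baseline_um,
               n_frames = length(idx))
  })
  do.call(rbind, rows)
}
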
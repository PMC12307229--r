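# Longitudinal actin-density profiles in microchannels and the
# inside/outside constriction enrichment ratio.

#' Segment the channel lumen from a brightfield frame
#'
#' Otsu threshold, largest connected component, holes filled.  A supplied
#' logical mask bypasses the computation unchanged.
#'
#' @param frame numeric Y x X brightfield frame, or a logical mask.
#' @return logical Y x X lumen mask.
#' @export
segment_channel <- function(frame) {
  if (is.logical(frame)) return(frame)
  stopifnot(is.matrix(frame))
  if (diff(range(frame)) <= 0) {
    stop("segment_channel: blank frame, no channel found", call. = FALSE)
  }
  thr <- otsu_threshold(frame)
  comp <- largest_component(frame > thr)
  if (!any(comp)) stop("segment_channel: no component found", call. = FALSE)
  t(EBImage::imageData(EBImage::fillHull(EBImage::Image(t(comp))))) > 0
}

#' Longitudinal density profile of a channel signal
#'
#' Per frame and image column, the mean signal over the lumen-mask pixels of
#' that column (a mean, so the profile is invariant to the channel height);
#' the time-max profile is the per-column maximum over frames.  Columns with
#' no mask pixels are absent (`NA`).  Optionally, the per-column median
#' profile of stated cell-free frames is subtracted first (background
#' correction).
#'
#' @param signal_frames numeric `T,Y,X` array (or `T,1,Y,X`).
#' @param mask logical Y x X lumen mask.
#' @param frames optional frame subset to profile (e.g. only frames in which
#'   the cell intersects the channel); default all.
#' @param background_frames optional indices of cell-free frames whose
#'   per-column median profile is subtracted (clipped at 0).
#' @param constriction_interval_px half-open, 0-based pixel column interval
#'   `c(x0, x1)` of the constriction, carried to [constriction_ratio()].
#' @return object of class `density_profile`: list with `profiles` (T' x X),
#'   `time_max_profile` (length X, NA outside the mask), `frames`,
#'   `channel_mask`, `constriction_interval_px`.
#' @export
density_profile <- function(signal_frames, mask, frames = NULL,
                            background_frames = NULL,
                            constriction_interval_px = NULL) {
  if (length(dim(signal_frames)) == 4L) {
    d <- dim(signal_frames)
    stopifnot(d[2L] == 1L)
    signal_frames <- array(signal_frames, dim = d[c(1L, 3L, 4L)])
  }
  d <- dim(signal_frames)
  stopifnot(length(d) == 3L, identical(dim(mask), d[2:3]))
  if (!any(mask)) stop("density_profile: empty mask", call. = FALSE)
  frames <- frames %||% seq_len(d[1L])
  col_n <- colSums(mask)
  prof_one <- function(t) {
    fr <- signal_frames[t, , , drop = TRUE]
    dim(fr) <- d[2:3]
    out <- colSums(fr * mask) / col_n
    out[col_n == 0L] <- NA_real_
    out
  }
  profiles <- t(vapply(frames, prof_one, numeric(d[3L])))
  if (!is.null(background_frames)) {
    bgp <- t(vapply(background_frames, prof_one, numeric(d[3L])))
    bg <- apply(bgp, 2L, stats::median)
    profiles <- sweep(profiles, 2L, bg)
    profiles[profiles < 0] <- 0
  }
  tmax <- apply(profiles, 2L, function(v) if (all(is.na(v))) NA_real_ else
    max(v, na.rm = TRUE))
  structure(list(profiles = profiles, time_max_profile = tmax,
                 frames = frames, channel_mask = mask,
                 constriction_interval_px = constriction_interval_px),
            class = "density_profile")
}

#' Inside/outside constriction density ratio
#'
#' Maximum of the time-max profile over the constriction interval divided by
#' its maximum outside the interval.
#'
#' @param profile a [density_profile()] (with a constriction interval), or
#'   pass `constriction_interval_px` here.
#' @param constriction_interval_px half-open 0-based `c(x0, x1)` columns.
#' @return dimensionless ratio.
#' @export
constriction_ratio <- function(profile, constriction_interval_px = NULL) {
  stopifnot(inherits(profile, "density_profile"))
  ci <- constriction_interval_px %||% profile$constriction_interval_px
  if (is.null(ci)) stop("constriction_ratio: no constriction interval", call. = FALSE)
  tmax <- profile$time_max_profile
  nX <- length(tmax)
  if (ci[1L] < 0 || ci[2L] > nX || ci[1L] >= ci[2L]) {
    stop("constriction_ratio: interval outside profile", call. = FALSE)
  }
  cols_in <- (ci[1L] + 1L):ci[2L]
  inside <- tmax[cols_in]; outside <- tmax[-cols_in]
  inside <- inside[is.finite(inside)]; outside <- outside[is.finite(outside)]
  if (!length(inside) || !length(outside)) {
    stop("constriction_ratio: empty inside or outside sub-profile", call. = FALSE)
  }
  mo <- max(outside)
  if (mo <= 0) stop("constriction_ratio: zero outside maximum", call. = FALSE)
  max(inside) / mo
}
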
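# Local maxima of deformation-magnitude and actin-intensity fields, and
# minimum deformation -> actin distances per Z-slice and timepoint.

#' Local maxima of a 2D field within a neighborhood radius
#'
#' A pixel is retained when it is the maximum of its Euclidean
#' radius-neighborhood and exceeds `min_prominence` above the field median.
#' When two candidates tie within one neighborhood, the lexicographically
#' smallest `(y, x)` is kept, and retained maxima are always more than
#' `radius_px` apart (non-maximum suppression ordered by value, then
#' coordinates).
#'
#' @param field numeric Y x X matrix.
#' @param radius_px neighborhood radius (>= 1).
#' @param min_prominence required height above the field median; default
#'   3x the median absolute deviation of the field.
#' @return data.frame with `y`, `x`, `value` (possibly 0 rows, e.g. for a
#'   constant field).
#' @export
local_maxima <- function(field, radius_px = 5, min_prominence = NULL) {
  stopifnot(is.matrix(field), radius_px >= 1)
  med <- stats::median(field)
  if (is.null(min_prominence)) min_prominence <- 3 * stats::mad(field)
  if (diff(range(field)) <= 0) {
    return(data.frame(y = integer(), x = integer(), value = numeric()))
  }
  # neighborhood maximum over the exact Euclidean disc (a morphological brush
  # would quantize the radius differently than the suppression step below)
  nY <- nrow(field); nX <- ncol(field)
  off <- disc_offsets(radius_px)
  nmax <- matrix(-Inf, nY, nX)
  for (i in seq_len(nrow(off))) {
    dy <- off$dy[i]; dx <- off$dx[i]
    ys <- max(1L, 1L + dy):min(nY, nY + dy)
    xs <- max(1L, 1L + dx):min(nX, nX + dx)
    sh <- matrix(-Inf, nY, nX)
    sh[ys - dy, xs - dx] <- field[ys, xs]
    nmax <- pmax(nmax, sh)
  }
  cand <- which(field >= nmax & field > med + min_prominence, arr.ind = TRUE)
  if (!nrow(cand)) {
    return(data.frame(y = integer(), x = integer(), value = numeric()))
  }
  vals <- field[cand]
  ord <- order(-vals, cand[, 1L], cand[, 2L])
  cand <- cand[ord, , drop = FALSE]
  vals <- vals[ord]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    kept <- cand[keep, , drop = FALSE]
    d2 <- (kept[, 1L] - cand[i, 1L])^2 + (kept[, 2L] - cand[i, 2L])^2
    if (min(d2) > radius_px^2) keep[i] <- TRUE
  }
  out <- data.frame(y = cand[keep, 1L], x = cand[keep, 2L], value = vals[keep])
  rownames(out) <- NULL
  out[order(out$y, out$x), ]
}

#' Minimum deformation-to-actin maxima distances per slice and timepoint
#'
#' For every deformation maximum, the Euclidean distance to the nearest actin
#' maximum in the same `(z, t)` slice, in micrometers.  Slices with no actin
#' maxima yield `NA` distances with `no_counterpart = TRUE` rather than
#' infinities.
#'
#' @param def_maxima,actin_maxima data.frames with columns `y`, `x` and
#'   optionally `z`, `t` (defaulting to slice 1); coordinates in pixels.
#' @param pixel_size_um pixel size.
#' @param symmetric also measure actin -> deformation distances and pool both
#'   directions (Hausdorff-style); default directed deformation -> actin.
#' @return list with `distances` (data.frame `z`, `t`, `y`, `x`,
#'   `min_distance_um`, `no_counterpart`) and `summary` (pooled median and
#'   IQR over finite distances).
#' @export
min_distances <- function(def_maxima, actin_maxima, pixel_size_um = 1,
                          symmetric = FALSE) {
  if (symmetric) {
    fwd <- min_distances(def_maxima, actin_maxima, pixel_size_um)
    rev <- min_distances(actin_maxima, def_maxima, pixel_size_um)
    distances <- rbind(cbind(fwd$distances, direction = "def_to_actin"),
                       cbind(rev$distances, direction = "actin_to_def"))
    fin <- distances$min_distance_um[is.finite(distances$min_distance_um)]
    return(list(distances = distances,
                summary = list(median_um = stats::median(fin), iqr_um = stats::IQR(fin),
                               n = length(fin),
                               n_no_counterpart = sum(distances$no_counterpart))))
  }
  norm <- function(df) {
    if (is.null(df$z)) df$z <- rep(1L, nrow(df))
    if (is.null(df$t)) df$t <- rep(1L, nrow(df))
    df
  }
  def_maxima <- norm(def_maxima); actin_maxima <- norm(actin_maxima)
  if (!nrow(def_maxima)) {
    stop("min_distances: no deformation maxima anywhere", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(def_maxima)), function(i) {
    z <- def_maxima$z[i]; t <- def_maxima$t[i]
    am <- actin_maxima[actin_maxima$z == z & actin_maxima$t == t, , drop = FALSE]
    if (!nrow(am)) {
      return(data.frame(z = z, t = t, y = def_maxima$y[i], x = def_maxima$x[i],
                        min_distance_um = NA_real_, no_counterpart = TRUE))
    }
    dd <- sqrt((am$y - def_maxima$y[i])^2 + (am$x - def_maxima$x[i])^2)
    data.frame(z = z, t = t, y = def_maxima$y[i], x = def_maxima$x[i],
               min_distance_um = min(dd) * pixel_size_um, no_counterpart = FALSE)
  })
  distances <- do.call(rbind, rows)
  fin <- distances$min_distance_um[is.finite(distances$min_distance_um)]
  list(distances = distances,
       summary = list(median_um = if (length(fin)) stats::median(fin) else NA_real_,
                      iqr_um = if (length(fin)) stats::IQR(fin) else NA_real_,
                      n = length(fin),
                      n_no_counterpart = sum(distances$no_counterpart)))
}
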
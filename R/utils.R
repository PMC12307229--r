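# Internal helpers shared across modules.

#' Otsu threshold of a numeric array
#'
#' Thin wrapper around [EBImage::otsu()] operating on an arbitrary numeric
#' array on its native intensity range.
#'
#' @param x numeric array/matrix with nonzero dynamic range.
#' @param levels number of histogram levels.
#' @return scalar threshold on the scale of `x`.
#' @keywords internal
otsu_threshold <- function(x, levels = 256L) {
  rng <- range(x, finite = TRUE)
  if (!all(is.finite(rng)) || diff(rng) <= 0) {
    stop("otsu_threshold: input has zero dynamic range", call. = FALSE)
  }
  EBImage::otsu(EBImage::Image(as.numeric(x), dim = c(length(x), 1L)),
                range = rng, levels = levels)
}

# 1D Gaussian kernel, truncated at 4 sigma, normalized.
gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  h <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

# Convolve a vector with a symmetric kernel, replicating the boundary values
# (avoids edge attenuation on short profiles).
smooth_vector <- function(x, kernel) {
  h <- (length(kernel) - 1L) %/% 2L
  if (h == 0L) return(x)
  xp <- c(rep(x[1L], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, kernel, sides = 2L))[(h + 1L):(h + length(x))]
}

# Running median with odd window, endpoints handled by shrinking the window.
running_median <- function(x, window) {
  stopifnot(window %% 2L == 1L)
  if (window <= 1L || length(x) < 3L) return(x)
  h <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1L, i - h):min(n, i + h)], na.rm = TRUE)
  }, numeric(1))
}

# Maximum projection of a [T,Z,Y,X] array over Z, returning [T,Y,X].
max_project_z <- function(arr) {
  d <- dim(arr)
  out <- arr[, 1L, , , drop = TRUE]
  dim(out) <- d[c(1L, 3L, 4L)]
  if (d[2L] > 1L) {
    for (z in seq(2L, d[2L])) {
      sl <- arr[, z, , , drop = TRUE]
      dim(sl) <- d[c(1L, 3L, 4L)]
      out <- pmax(out, sl)
    }
  }
  out
}

# Integer pixel offsets of a Euclidean disc of given radius.
disc_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g <- g[g$dy^2 + g$dx^2 <= radius^2 & !(g$dy == 0 & g$dx == 0), , drop = FALSE]
  g
}

# Standard error of the mean (NA for n < 2).
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
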
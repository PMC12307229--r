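#' Multichannel time-lapse image stack
#'
#' The universal raster container of the package: a named list of per-channel
#' arrays in `T,Z,Y,X` order (2D time-lapse carries a singleton Z axis),
#' plus the physical calibrations every downstream measurement needs.
#'
#' @param channels named list of numeric 4D arrays, all with identical
#'   `c(T, Z, Y, X)` dimensions.  2D movies may be supplied as `T,Y,X` arrays
#'   and gain a singleton Z axis.
#' @param voxel_size_um named numeric `c(z=, y=, x=)` in micrometers.
#' @param frame_interval_s frame spacing in seconds.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size_um = c(z = 0.1, y = 0.16, x = 0.16),
                        frame_interval_s = 30) {
  stopifnot(is.list(channels), length(channels) >= 1L, !is.null(names(channels)))
  channels <- lapply(channels, function(a) {
    if (length(dim(a)) == 3L) dim(a) <- c(dim(a)[1L], 1L, dim(a)[2L], dim(a)[3L])
    stopifnot(length(dim(a)) == 4L)
    a
  })
  d0 <- dim(channels[[1L]])
  for (a in channels) stopifnot(identical(dim(a), d0))
  voxel_size_um <- voxel_size_um[c("z", "y", "x")]
  stopifnot(all(is.finite(voxel_size_um)), all(voxel_size_um > 0),
            is.finite(frame_interval_s), frame_interval_s > 0)
  structure(list(channels = channels,
                 dim = stats::setNames(d0, c("t", "z", "y", "x")),
                 voxel_size_um = voxel_size_um,
                 frame_interval_s = frame_interval_s),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat("<image_stack> ", paste(names(x$dim), x$dim, sep = "=", collapse = " "),
      " channels: ", paste(names(x$channels), collapse = ", "), "\n",
      " voxel (um): ", paste(names(x$voxel_size_um), signif(x$voxel_size_um, 3),
                             sep = "=", collapse = " "),
      "  dt = ", x$frame_interval_s, " s\n", sep = "")
  invisible(x)
}

#' Write an image stack to disk
#'
#' Writes a multi-page 32-bit float TIFF (pages ordered T, then Z, then C)
#' together with a JSON sidecar (`<path>.json`) recording axes, shape,
#' channel names, calibrations and the intensity scale used, so that
#' [read_stack()] restores the stack losslessly to float precision.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- stack$dim
  hi <- max(1e-12, max(vapply(stack$channels, max, numeric(1))))
  lo <- min(0, min(vapply(stack$channels, min, numeric(1))))
  scale <- hi - lo
  pages <- vector("list", d[["t"]] * d[["z"]] * length(stack$channels))
  i <- 1L
  for (t in seq_len(d[["t"]])) for (z in seq_len(d[["z"]])) {
    for (ch in stack$channels) {
      pg <- ch[t, z, , , drop = TRUE]
      dim(pg) <- d[c("y", "x")]
      pages[[i]] <- (pg - lo) / scale
      i <- i + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  meta <- list(axes = "TZCYX",
               shape = as.integer(c(d[["t"]], d[["z"]], length(stack$channels),
                                    d[["y"]], d[["x"]])),
               channel_names = names(stack$channels),
               voxel_size_um = as.list(stack$voxel_size_um),
               frame_interval_s = stack$frame_interval_s,
               intensity_offset = lo, intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack from disk
#'
#' Reads a TIFF written by [write_stack()] (using its JSON sidecar), or an
#' arbitrary multi-page TIFF given an explicit `axis_spec` describing the page
#' order and shape.  The result is always in canonical `T,Z,C,Y,X` order; a
#' 2D time-lapse gains a singleton Z axis.
#'
#' @param path TIFF path.
#' @param axis_spec optional list with elements `axes` (a permutation of the
#'   characters in `"TZCYX"`, page-major first; `"Z"` and/or `"C"` may be
#'   omitted for singleton axes) and `shape` (integer sizes in that order).
#'   Ignored when a sidecar is present.
#' @param voxel_size_um,frame_interval_s calibrations used when no sidecar
#'   exists.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, axis_spec = NULL,
                       voxel_size_um = c(z = 0.1, y = 0.16, x = 0.16),
                       frame_interval_s = 30) {
  stopifnot(file.exists(path))
  side <- paste0(path, ".json")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    shape <- as.integer(meta$shape)   # T Z C Y X
    axes <- strsplit(meta$axes, "")[[1L]]
  } else {
    if (is.null(axis_spec)) {
      stop("read_stack: no sidecar metadata; supply axis_spec (axes missing: TZC order)",
           call. = FALSE)
    }
    axes <- strsplit(toupper(axis_spec$axes), "")[[1L]]
    bad <- setdiff(axes, c("T", "Z", "C", "Y", "X"))
    if (length(bad)) {
      stop("read_stack: unknown axis '", bad[1L], "' in axis_spec", call. = FALSE)
    }
    for (ax in c("T", "Y", "X")) {
      if (!ax %in% axes) {
        stop("read_stack: axis_spec does not resolve axis '", ax, "'", call. = FALSE)
      }
    }
    sh <- as.integer(axis_spec$shape)
    names(sh) <- axes
    shape <- c(sh[["T"]],
               if ("Z" %in% axes) sh[["Z"]] else 1L,
               if ("C" %in% axes) sh[["C"]] else 1L,
               sh[["Y"]], sh[["X"]])
    # page-major order of the file must be (slowest..fastest) the non-YX axes
    meta <- list(channel_names = paste0("ch", seq_len(shape[3L])),
                 voxel_size_um = as.list(voxel_size_um),
                 frame_interval_s = frame_interval_s,
                 intensity_offset = 0, intensity_scale = 1)
  }
  nT <- shape[1L]; nZ <- shape[2L]; nC <- shape[3L]; nY <- shape[4L]; nX <- shape[5L]
  if (length(pages) != nT * nZ * nC) {
    stop("read_stack: file has ", length(pages), " pages but metadata implies ",
         nT * nZ * nC, call. = FALSE)
  }
  # page-major decoding: axes as listed (minus YX), slowest first
  page_axes <- setdiff(axes, c("Y", "X"))
  sizes <- c(T = nT, Z = nZ, C = nC)[page_axes]
  chn <- as.character(unlist(meta$channel_names))
  channels <- stats::setNames(
    lapply(seq_len(nC), function(i) array(0, dim = c(nT, nZ, nY, nX))), chn)
  for (i in seq_along(pages)) {
    rem <- i - 1L
    idx <- c(T = 1L, Z = 1L, C = 1L)
    for (ax in rev(page_axes)) {           # fastest-varying axis is last listed
      idx[ax] <- rem %% sizes[[ax]] + 1L
      rem <- rem %/% sizes[[ax]]
    }
    channels[[idx[["C"]]]][idx[["T"]], idx[["Z"]], , ] <-
      pages[[i]] * meta$intensity_scale + meta$intensity_offset
  }
  vs <- unlist(meta$voxel_size_um)[c("z", "y", "x")]
  image_stack(channels, voxel_size_um = vs,
              frame_interval_s = meta$frame_interval_s)
}
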
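# End-to-end orchestrations chaining the stages into the two main analyses
# (pushing-force microscopy; central-pool/protrusion coupling), plus config
# handling and a thin group-comparison helper for output tables.
# Pipelines add no computation of their own: every number in an output table
# is reproducible by calling the underlying operations with the same config.

#' Load a run configuration
#'
#' @param config a list, or the path of a YAML/JSON file.
#' @return validated config list.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cal <- config$calibration %||% list()
  for (f in intersect(names(cal), c("pixel_size_um", "z_step_um", "frame_interval_s"))) {
    if (!is.numeric(cal[[f]]) || cal[[f]] <= 0) {
      stop("load_run_config: calibration ", f, " must be > 0", call. = FALSE)
    }
  }
  config
}

write_table <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
}

log_lines <- function(log, ...) c(log, paste0(...))

#' Pushing-force microscopy pipeline
#'
#' Chains bead detection, kymograph extraction, Otsu edge tracking,
#' windowed channel traces, K-means contribution classification,
#' `none`-frame re-baselining and per-region displacement summaries.  Input
#' is either a simulated scene (`config$simulate`, a list of
#' [bead_scene_params()] overrides) or a stack on disk (`config$input$path`
#' with a `config$channels` role map).  Deterministic for a fixed
#' `config$seed`.
#'
#' @param config list or YAML/JSON path; recognized blocks: `seed`,
#'   `simulate`, `input`, `channels` (roles bead/actin/nucleus -> channel
#'   name), `detection` (args of [detect_beads()]), `kymograph`
#'   (`xy_halfwidth_px`), `traces` (`halfwidth_px`), `classify` (`k`).
#' @param out_dir optional output directory; tables (`bead_records.csv`,
#'   `displacement_traces.csv`, `region_summary.csv`), the echoed config and
#'   a structured log are written there.
#' @return (invisibly) list with `beads`, `traces_table`, `summary_table`,
#'   `max_displacements`, `log`, and `truth` when simulated.
#' @export
run_pushforce_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- load_run_config(config)
  seed <- cfg$seed %||% 1L
  log <- character()
  truth <- NULL
  if (!is.null(cfg$input$path)) {
    stack <- read_stack(cfg$input$path, axis_spec = cfg$input$axis_spec)
    log <- log_lines(log, "input: ", cfg$input$path)
  } else {
    sim <- cfg$simulate %||% list()
    params <- do.call(bead_scene_params,
                      utils::modifyList(sim, list(seed = seed), keep.null = TRUE))
    scene <- generate_bead_stack(params)
    stack <- scene$stack
    truth <- scene$truth
    log <- log_lines(log, "input: simulated bead scene, seed ", seed)
  }
  roles <- utils::modifyList(list(bead = "bead", actin = "actin",
                                  nucleus = "nucleus"), cfg$channels %||% list())
  for (r in unlist(roles)) {
    if (!r %in% names(stack$channels)) {
      stop("run_pushforce_pipeline: channel '", r, "' not in stack", call. = FALSE)
    }
  }
  bead_ch <- stack$channels[[roles$bead]]
  actin_ch <- stack$channels[[roles$actin]]
  nuc_ch <- stack$channels[[roles$nucleus]]
  z_step <- stack$voxel_size_um[["z"]]
  dt <- stack$frame_interval_s

  det_args <- cfg$detection %||% list()
  tr_hw <- (cfg$traces %||% list())$halfwidth_px %||% 10L
  det_args$edge_margin_px <- det_args$edge_margin_px %||% tr_hw
  beads <- do.call(detect_beads, c(list(bead_channel = bead_ch), det_args))
  log <- log_lines(log, "detected components: ", nrow(beads),
                   "; accepted: ", sum(beads$accepted))
  for (i in which(!beads$accepted)) {
    log <- log_lines(log, "rejected bead ", beads$id[i], ": ",
                     beads$rejection_reason[i])
  }

  traces_rows <- list(); summary_rows <- list(); maxd <- list()
  k <- (cfg$classify %||% list())$k %||% 3L
  hw_k <- (cfg$kymograph %||% list())$xy_halfwidth_px %||% 2L
  for (i in which(beads$accepted)) {
    bead <- beads[i, , drop = FALSE]
    res <- tryCatch({
      kym <- extract_kymograph(bead_ch, bead, xy_halfwidth_px = hw_k,
                               z_step_um = z_step, frame_interval_s = dt)
      trace <- track_edge(kym)
      ctr <- extract_channel_traces(actin_ch, nuc_ch, bead, halfwidth_px = tr_hw)
      labels <- classify_frames(ctr, k = k, seed = seed + bead$id)
      trace <- tryCatch(set_trace_baseline(trace, labels), error = function(e) trace)
      summ <- summarize_region_displacement(trace, labels,
                                            baseline_um = trace$baseline_um)
      list(trace = trace, labels = labels, summ = summ)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      log <- log_lines(log, "bead ", bead$id, " skipped: ", conditionMessage(res))
      next
    }
    nT <- length(res$trace$edge_z_um)
    traces_rows[[length(traces_rows) + 1L]] <- data.frame(
      bead_id = bead$id, frame = seq_len(nT), time_s = (seq_len(nT) - 1) * dt,
      edge_z_um = res$trace$edge_z_um,
      displacement_um = res$trace$displacement_um,
      valid = res$trace$valid, label = res$labels$labels)
    summary_rows[[length(summary_rows) + 1L]] <-
      cbind(bead_id = bead$id, res$summ)
    maxd[[as.character(bead$id)]] <- max_displacement(res$trace)
  }
  traces_table <- if (length(traces_rows)) do.call(rbind, traces_rows) else
    data.frame()
  summary_table <- if (length(summary_rows)) do.call(rbind, summary_rows) else
    data.frame()
  if (!length(maxd)) {
    warning("run_pushforce_pipeline: zero accepted beads analysed")
  }
  max_table <- data.frame(bead_id = as.integer(names(maxd)),
                          max_displacement_um = as.numeric(unlist(maxd)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(beads, out_dir, "bead_records.csv")
    write_table(traces_table, out_dir, "displacement_traces.csv")
    write_table(summary_table, out_dir, "region_summary.csv")
    write_table(max_table, out_dir, "max_displacements.csv")
    yaml::write_yaml(cfg, file.path(out_dir, "config_echo.yaml"))
    writeLines(log, file.path(out_dir, "pipeline_log.txt"))
  }
  invisible(list(beads = beads, traces_table = traces_table,
                 summary_table = summary_table, max_displacements = max_table,
                 log = log, truth = truth))
}

# series extraction for one segmented, tracked cell movie: background-
# corrected integrated actin in the central pool and in the leading-edge
# rim band (the lamellipodial protrusion region).
coupling_series <- function(actin_frames, cell_masks, pool_masks,
                            centroids, depth_px = 6L) {
  nT <- length(actin_frames)
  central <- rep(NA_real_, nT); protrusion <- rep(NA_real_, nT)
  for (t in seq_len(nT)) {
    if (!any(cell_masks[[t]])) next
    bg <- stats::median(actin_frames[[t]][!cell_masks[[t]]])
    if (any(pool_masks[[t]])) {
      central[t] <- integrated_intensity(actin_frames[[t]], pool_masks[[t]], bg)
    }
    i0 <- max(1L, t - 2L); i1 <- min(nT, t + 2L)
    dir <- centroids[i1, ] - centroids[i0, ]
    lem <- leading_edge_mask(cell_masks[[t]], direction = dir,
                             depth_px = depth_px)
    if (any(lem)) {
      protrusion[t] <- integrated_intensity(actin_frames[[t]], lem, bg)
    }
  }
  list(central = central, protrusion = protrusion)
}

# linear interpolation over interior NAs, constant extrapolation at the ends
fill_na <- function(v) {
  if (!anyNA(v)) return(v)
  ok <- which(is.finite(v))
  if (length(ok) < 2L) return(v)
  stats::approx(ok, v[ok], xout = seq_along(v), rule = 2L)$y
}

#' Central-pool / protrusion coupling pipeline
#'
#' Simulates (or loads) single-cell 2D movies, segments cell and central pool
#' per frame, links tracks (strict >10-frame filter), extracts
#' background-corrected central-pool and protrusion (gained-region) actin
#' series, cross-correlates them per cell, and pools the curves across cells.
#'
#' @param config list or YAML/JSON path; recognized: `seed`, `n_cells`,
#'   `coupling` (`coefficient`, `lag_frames`), `simulate`
#'   ([migration_scene_params()] overrides), `max_lag`, `significance`
#'   (`enabled`, `n_permutations`).
#' @param out_dir optional output directory (`per_cell_correlations.csv`,
#'   `pooled_correlation.csv`, `cell_summary.csv`, config echo, log).
#' @return (invisibly) list with `per_cell` (list of `cross_correlation`),
#'   `pooled` (data.frame), `cell_summary` (r at lag 0, peak lag, optional
#'   permutation p), `log`.
#' @export
run_coupling_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- load_run_config(config)
  seed <- cfg$seed %||% 1L
  n_cells <- cfg$n_cells %||% 10L
  coup <- utils::modifyList(list(coefficient = -0.8, lag_frames = 0L),
                            cfg$coupling %||% list())
  max_lag <- cfg$max_lag %||% 10L
  sig_cfg <- utils::modifyList(list(enabled = FALSE, n_permutations = 1000L),
                               cfg$significance %||% list())
  params <- do.call(migration_scene_params, cfg$simulate %||% list())
  log <- character()
  per_cell <- list(); summary_rows <- list()
  for (ci in seq_len(n_cells)) {
    cell_seed <- seed * 1000L + ci
    scene <- generate_migration_movie(params, coup$coefficient,
                                      coup$lag_frames, seed = cell_seed)
    actin <- scene$stack$channels$actin
    nT <- dim(actin)[1L]
    frames <- lapply(seq_len(nT), function(t) {
      fr <- actin[t, 1L, , , drop = TRUE]
      dim(fr) <- dim(actin)[3:4]
      fr
    })
    segs <- lapply(frames, segment_cell)
    label_frames <- lapply(segs, function(s) {
      m <- matrix(0L, nrow(s$cell), ncol(s$cell)); m[s$cell] <- 1L; m
    })
    tracks <- link_tracks(label_frames,
                          pixel_size_um = params$pixel_size_um,
                          frame_interval_s = params$frame_interval_s)
    if (!length(tracks)) {
      log <- log_lines(log, "cell ", ci, ": no track surviving the filter")
      next
    }
    tf <- tracks[[1L]]$frames
    depth_px <- max(2L, round(params$lamellipodium_depth_um / params$pixel_size_um))
    ser <- coupling_series(frames[tf],
                           lapply(segs[tf], `[[`, "cell"),
                           lapply(segs[tf], `[[`, "pool"),
                           centroids = tracks[[1L]]$centroid_px,
                           depth_px = depth_px)
    x <- fill_na(ser$protrusion); y <- fill_na(ser$central)
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    cc <- tryCatch(cross_correlate(x, y, max_lag = max_lag),
                   error = function(e) e)
    if (inherits(cc, "error")) {
      log <- log_lines(log, "cell ", ci, ": correlation absent (",
                       conditionMessage(cc), ")")
      next
    }
    p <- NA_real_
    if (isTRUE(sig_cfg$enabled)) {
      p <- lag_significance(x, y, max_lag = max_lag,
                            n_permutations = sig_cfg$n_permutations,
                            seed = cell_seed)$p_value
    }
    per_cell[[length(per_cell) + 1L]] <- cc
    summary_rows[[length(summary_rows) + 1L]] <- data.frame(
      cell = ci, n_frames = cc$n_frames, r_lag0 = cc$r[cc$lags == 0L],
      peak_lag = cc$peak_lag, peak_r = cc$peak_r, p_value = p)
  }
  if (!length(per_cell)) {
    warning("run_coupling_pipeline: no cell produced a correlation")
    return(invisible(list(per_cell = list(), pooled = data.frame(),
                          cell_summary = data.frame(), log = log)))
  }
  pooled <- pool_cross_correlations(per_cell)
  cell_summary <- do.call(rbind, summary_rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    percell_tab <- do.call(rbind, lapply(seq_along(per_cell), function(i) {
      data.frame(cell = cell_summary$cell[i], lag = per_cell[[i]]$lags,
                 r = per_cell[[i]]$r)
    }))
    write_table(percell_tab, out_dir, "per_cell_correlations.csv")
    write_table(pooled, out_dir, "pooled_correlation.csv")
    write_table(cell_summary, out_dir, "cell_summary.csv")
    yaml::write_yaml(cfg, file.path(out_dir, "config_echo.yaml"))
    writeLines(log, file.path(out_dir, "pipeline_log.txt"))
  }
  invisible(list(per_cell = per_cell, pooled = pooled,
                 cell_summary = cell_summary, log = log))
}

#' Thin two-group comparison helper for result tables
#'
#' Convenience wrapper reporting a normality check (Shapiro-Wilk) and the
#' matching two-sample test (Student's t when both groups look normal,
#' Mann-Whitney otherwise); categorical presence/absence tables go through
#' Fisher's exact test via `stats::fisher.test` directly.
#'
#' @param values numeric vector.
#' @param groups two-level factor/character of the same length.
#' @return list with `test`, `p_value`, `group_means`.
#' @export
group_stats <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2L, length(values) == length(groups))
  sp <- split(values, groups)
  normal <- all(vapply(sp, function(v) {
    if (length(v) < 3L || stats::sd(v) == 0) return(FALSE)
    stats::shapiro.test(v)$p.value > 0.05
  }, logical(1)))
  if (normal) {
    tt <- stats::t.test(values ~ groups)
    list(test = "t", p_value = tt$p.value,
         group_means = vapply(sp, mean, numeric(1)))
  } else {
    wt <- stats::wilcox.test(values ~ groups, exact = FALSE)
    list(test = "mann_whitney", p_value = wt$p.value,
         group_means = vapply(sp, mean, numeric(1)))
  }
}
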
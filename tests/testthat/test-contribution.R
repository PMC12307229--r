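# Windowed channel traces, K-means compartment classification and per-region
# displacement summaries.

test_that("channel traces sum the window over Z and track the generator truth", {
  zch <- array(0, dim = c(3L, 2L, 30L, 30L))
  bead <- data.frame(id = 1L, y = 15, x = 15, area_px = 9, accepted = TRUE,
                     rejection_reason = "none")
  tr0 <- extract_channel_traces(zch, zch, bead, halfwidth_px = 5)
  expect_equal(tr0$actin, rep(0, 3L))
  expect_equal(tr0$nucleus, rep(0, 3L))

  expect_error(extract_channel_traces(zch, zch, bead, halfwidth_px = 15),
               "bounds")

  p <- small_bead_params(n_beads = 2L)
  sc <- generate_bead_stack(p)
  beads <- detect_beads(sc$stack$channels$bead)
  b <- beads[which(beads$accepted)[1L], , drop = FALSE]
  j <- which.min((sc$truth$bead_xy_px[, "y"] - b$y)^2 +
                   (sc$truth$bead_xy_px[, "x"] - b$x)^2)
  tr <- extract_channel_traces(sc$stack$channels$actin,
                               sc$stack$channels$nucleus, b)
  truth_lab <- sc$truth$labels[j, ]
  expect_true(mean(tr$actin[truth_lab == "central_actin"]) >
                mean(tr$actin[truth_lab != "central_actin"]))
  expect_equal(which.max(tr$actin) %in% which(truth_lab == "central_actin"), TRUE)
})

test_that("well-separated plateau traces classify perfectly", {
  set.seed(42)
  lens <- c(10L, 8L, 6L, 8L, 10L)
  levels <- c(10, 100, 1000, 100, 10)
  actin <- unlist(mapply(function(l, n) stats::rnorm(n, l, 1), levels, lens))
  truth <- rep(c("none", "cytoplasm", "central_actin", "cytoplasm", "none"), lens)
  lab <- classify_frames(make_traces(actin), k = 3L, seed = 7L)
  expect_equal(mean(lab$labels == truth), 1)
  expect_true(all(diff(lab$cluster_means) > 0))
  expect_equal(lab$k_used, 3L)
})

test_that("k = 2 never assigns central_actin", {
  set.seed(1)
  actin <- c(stats::rnorm(12, 10, 1), stats::rnorm(12, 200, 1))
  lab <- classify_frames(make_traces(actin), k = 2L, seed = 3L)
  expect_false("central_actin" %in% lab$labels)
  expect_equal(lab$labels, rep(c("none", "cytoplasm"), each = 12L))
})

test_that("nucleus override fires only on genuinely bimodal nucleus traces", {
  set.seed(2)
  lens <- c(10L, 6L, 10L)
  actin <- unlist(mapply(function(l, n) stats::rnorm(n, l, 1),
                         c(10, 1000, 10), lens))
  flat_nuc <- stats::rnorm(sum(lens), 5, 1)
  lab <- classify_frames(make_traces(actin, flat_nuc), k = 3L, seed = 4L)
  expect_false("nucleus" %in% lab$labels)

  # nucleus passage coincides with the high-actin plateau: nucleus wins
  nuc <- c(stats::rnorm(10, 5, 1), stats::rnorm(6, 500, 5), stats::rnorm(10, 5, 1))
  lab2 <- classify_frames(make_traces(actin, nuc), k = 3L, seed = 4L)
  expect_equal(lab2$labels[11:16], rep("nucleus", 6L))
  expect_false("nucleus" %in% lab2$labels[-(11:16)])
})

test_that("degenerate actin traces raise a clustering error", {
  expect_error(classify_frames(make_traces(rep(5, 20L)), k = 3L),
               "degenerate")
})

test_that("classification is seed-stable and noise-only traces stay 'none'", {
  set.seed(3)
  actin <- unlist(mapply(function(l, n) stats::rnorm(n, l, 1),
                         c(10, 100, 1000), c(10L, 8L, 8L)))
  l1 <- classify_frames(make_traces(actin), seed = 5L)
  l2 <- classify_frames(make_traces(actin), seed = 5L)
  expect_identical(l1$labels, l2$labels)
  agree <- vapply(1:10, function(s) {
    mean(classify_frames(make_traces(actin), seed = s)$labels == l1$labels)
  }, numeric(1))
  expect_true(all(agree >= 0.99))

  noise <- stats::rnorm(30, 50, 2)    # no cell ever under the bead
  ln <- classify_frames(make_traces(noise), k = 3L, seed = 6L)
  expect_true(all(ln$labels == "none"))
})

test_that("label-measure consistency holds on generator scenes", {
  p <- small_bead_params(n_beads = 3L)
  sc <- generate_bead_stack(p)
  beads <- detect_beads(sc$stack$channels$bead)
  for (i in which(beads$accepted)) {
    tr <- extract_channel_traces(sc$stack$channels$actin,
                                 sc$stack$channels$nucleus,
                                 beads[i, , drop = FALSE])
    lab <- classify_frames(tr, k = 3L, seed = 8L)$labels
    m <- vapply(c("none", "cytoplasm", "central_actin"),
                function(rg) if (any(lab == rg)) mean(tr$actin[lab == rg]) else NA_real_,
                numeric(1))
    m <- m[is.finite(m)]
    if (length(m) >= 2L) expect_true(all(diff(m) > 0))
  }
})

test_that("region summaries are baseline-anchored and order-invariant", {
  edge <- c(1, 1, 1.2, 1.8, 1.8, 1.4, 1, 1)
  labels <- c("none", "none", "cytoplasm", "central_actin", "central_actin",
              "cytoplasm", "none", "none")
  tr <- make_trace(edge)
  s <- summarize_region_displacement(tr, labels)
  expect_equal(s$mean_displacement_um[s$region == "none"], 0)
  expect_equal(s$mean_displacement_um[s$region == "central_actin"], 0.8)
  expect_equal(s$mean_displacement_um[s$region == "cytoplasm"], 0.3)
  expect_false("nucleus" %in% s$region)      # absent, not zero

  perm <- sample(seq_along(edge))
  s2 <- summarize_region_displacement(make_trace(edge[perm]), labels[perm])
  expect_equal(s2[order(s2$region), ], s[order(s$region), ],
               ignore_attr = TRUE)

  all_none <- summarize_region_displacement(make_trace(rep(2, 5L)),
                                            rep("none", 5L))
  expect_equal(all_none$region, "none")
  expect_equal(all_none$mean_displacement_um, 0)

  expect_error(summarize_region_displacement(tr, rep("cytoplasm", 8L)),
               "baseline")
  sb <- summarize_region_displacement(tr, rep("cytoplasm", 8L), baseline_um = 1)
  expect_equal(sb$mean_displacement_um, mean(edge) - 1)
})
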
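# Synthetic generators: determinism, truth round-trips, mirror construction.

test_that("generators are deterministic per seed", {
  p <- pattern_params(jitter_sd_um = 3, seed = 9L)
  g1 <- make_nerve_pattern(p); g2 <- make_nerve_pattern(p)
  expect_identical(g1$pattern$nodes, g2$pattern$nodes)
  expect_identical(g1$band$mask, g2$band$mask)
  e1 <- make_explant_image(seed = 9); e2 <- make_explant_image(seed = 9)
  expect_identical(e1$mask, e2$mask)
  d1 <- make_expression_dataset(n_probes = 200, n_left_enriched = 3,
                                n_right_enriched = 3, seed = 9)
  d2 <- make_expression_dataset(n_probes = 200, n_left_enriched = 3,
                                n_right_enriched = 3, seed = 9)
  expect_identical(d1$matrix$expr, d2$matrix$expr)
  c1 <- make_cell_assay(seed = 9); c2 <- make_cell_assay(seed = 9)
  expect_identical(c1$table, c2$table)
  b1 <- make_blot_replicates(noise_cv = 0.2, seed = 9)
  b2 <- make_blot_replicates(noise_cv = 0.2, seed = 9)
  expect_identical(b1$replicates, b2$replicates)
  # and seeds do not leak into the session RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(make_expression_dataset(n_probes = 50, seed = 2,
                                                 n_left_enriched = 1,
                                                 n_right_enriched = 1))
  expect_identical(runif(1), before)
})

test_that("zero jitter makes patterns seed-independent", {
  p1 <- pattern_params(jitter_sd_um = 0, seed = 1L)
  p2 <- pattern_params(jitter_sd_um = 0, seed = 999L)
  expect_identical(make_nerve_pattern(p1)$pattern$nodes,
                   make_nerve_pattern(p2)$pattern$nodes)
})

test_that("truth records round-trip through JSON", {
  g <- make_nerve_pattern(preset_pattern_params("E14.5-right", seed = 3L))
  rt <- jsonlite::fromJSON(jsonlite::toJSON(g$truth, digits = NA,
                                            auto_unbox = TRUE))
  expect_equal(rt, g$truth, tolerance = 1e-12)
  ds <- make_expression_dataset(n_probes = 100, n_left_enriched = 2,
                                n_right_enriched = 2, seed = 4)
  rt2 <- jsonlite::fromJSON(jsonlite::toJSON(ds$truth, digits = NA,
                                             auto_unbox = TRUE))
  expect_equal(rt2, ds$truth, tolerance = 1e-12)
})

test_that("flipping the side mirrors the construction", {
  pl <- pattern_params(side = "left", n_secondary = 5L, jitter_sd_um = 0)
  pr <- pattern_params(side = "right", n_secondary = 5L, jitter_sd_um = 0)
  gl <- make_nerve_pattern(pl); gr <- make_nerve_pattern(pr)
  ex <- gl$truth$entry[1]
  mirrored <- mirror_pattern(gl$pattern)
  mirrored$nodes$x <- mirrored$nodes$x + 2 * ex
  expect_equal(mirrored$nodes, gr$pattern$nodes, tolerance = 1e-12)
  expect_identical(mirrored$side, gr$pattern$side)
})

test_that("patterns with no secondaries yield zero crossings", {
  g <- make_nerve_pattern(pattern_params(n_secondary = 0L))
  expect_identical(branch_crossings(g$pattern, fit_endplate_axis(g$band)),
                   0L)
})

test_that("noiseless planted folds behave at the threshold boundary", {
  exact15 <- make_expression_dataset(n_probes = 300, n_left_enriched = 10,
                                     n_right_enriched = 10, fold = 1.5,
                                     noise_sigma_log2 = 0, seed = 5)
  gs <- detect_lateralized(exact15$matrix)
  expect_length(gs$left_enriched, 0)
  expect_length(gs$right_enriched, 0)
  fold2 <- make_expression_dataset(n_probes = 300, n_left_enriched = 10,
                                   n_right_enriched = 10, fold = 2,
                                   noise_sigma_log2 = 0, seed = 5)
  gs2 <- detect_lateralized(fold2$matrix)
  expect_setequal(gs2$left_enriched, fold2$truth$left_enriched)
  expect_setequal(gs2$right_enriched, fold2$truth$right_enriched)
})

test_that("cell assay calibrates to the planted activity probabilities", {
  none <- make_cell_assay(p_active_left = 0, p_active_right = 0, seed = 6)
  z <- zymography_fraction(none$table)
  expect_equal(z$per_side$percent, c(0, 0))
  nomark <- make_cell_assay(p_marker = 0, seed = 6)
  expect_error(zymography_fraction(nomark$table), class = "NoMarkerCells")
  folds <- vapply(1:20, function(s) {
    zymography_fraction(make_cell_assay(seed = s)$table)$fold
  }, numeric(1))
  expect_equal(mean(folds), 0.379 / 0.234, tolerance = 0.1)
})

test_that("noiseless blot replicates carry the true ratio exactly", {
  br <- make_blot_replicates(n = 5, true_ratio = 1.22, noise_cv = 0,
                             seed = 7)
  nb <- normalize_blot_pairs(br$replicates)
  expect_equal(mean(nb$ratio), 1.22, tolerance = 1e-12)
  unit <- make_blot_replicates(true_ratio = 1, seed = 8)
  nbu <- normalize_blot_pairs(unit$replicates)
  expect_equal(nbu$left, nbu$right, tolerance = 1e-12)
})

test_that("single-fascicle explant area tracks width x radial length", {
  e <- make_explant_image(n_fascicles = 1, fascicle_width = 5,
                          max_extent = 150, seed = 10)
  prof <- build_rings(e$border, 25, dim(e$mask))
  oa <- outgrowth_area(e$mask, prof)
  expect_equal(oa$total_area, 5 * 150, tolerance = 0.2 * 5 * 150)
})

test_that("parameter validation rejects impossible settings", {
  expect_error(pattern_params(split_angle_deg = 190),
               class = "InvalidParams")
  expect_error(preset_pattern_params("E16.5-left"),
               class = "InvalidParams")
  expect_error(make_expression_dataset(n_probes = 10, n_left_enriched = 9,
                                       n_right_enriched = 9),
               class = "InvalidParams")
  expect_error(make_blot_replicates(true_ratio = -1),
               class = "InvalidParams")
  expect_error(make_cell_assay(p_marker = 1.2), class = "InvalidParams")
})
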
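# Morphometric measures on hand-built shapes and patterns.

rect_band <- function(nr = 50, nc = 300, pad = 20, scale = 1) {
  m <- matrix(FALSE, nr + 2 * pad, nc + 2 * pad)
  m[pad + seq_len(nr), pad + seq_len(nc)] <- TRUE
  endplate_band(m, scale)
}

test_that("endplate axis is the principal axis through the centroid", {
  band <- rect_band()
  ax <- fit_endplate_axis(band)
  expect_equal(ax$direction, c(1, 0), tolerance = 1e-8)
  co <- which(band$mask, arr.ind = TRUE)
  expect_equal(ax$point, c(mean(co[, 2]) - 1, mean(co[, 1]) - 1),
               tolerance = 1e-8)

  # rotated rectangle: direction recovered within 0.5 degrees
  co0 <- cbind(rep(0:299, each = 50), rep(0:49, times = 300))
  R <- rotation_matrix(30)
  rot <- round(t(R %*% t(co0))) + 100
  m <- matrix(FALSE, 500, 500)
  m[cbind(rot[, 2] + 1, rot[, 1] + 1)] <- TRUE
  ax30 <- fit_endplate_axis(endplate_band(m))
  ang <- atan2(ax30$direction[2], ax30$direction[1]) * 180 / pi
  expect_lt(abs(ang - 30), 0.5)
})

test_that("isotropic masks have no meaningful tangent", {
  sq <- matrix(TRUE, 50, 50)
  expect_error(fit_endplate_axis(endplate_band(sq)),
               class = "DegenerateShape")
  expect_error(endplate_band(matrix(FALSE, 5, 5)), class = "EmptyMask")
})

test_that("defasciculation distance is the perpendicular point-line distance", {
  horiz <- line2d(c(0, 100), c(1, 0))
  expect_equal(defasciculation_distance(c(50, 100), horiz), 0)
  expect_equal(defasciculation_distance(c(0, 0), horiz), 100)
  diag45 <- line2d(c(0, 50), c(1, 1))
  expect_equal(defasciculation_distance(c(0, 0), diag45), 35.355,
               tolerance = 1e-3)
  # invariant under a rigid motion of both inputs
  R <- rotation_matrix(73); tr <- c(-40, 11)
  expect_equal(
    defasciculation_distance(drop(R %*% c(0, 0)) + tr,
                             transform_line(diag45, R, tr)),
    defasciculation_distance(c(0, 0), diag45), tolerance = 1e-9)
})

test_that("endplate thickness averages perpendicular bin extents", {
  expect_equal(endplate_thickness(rect_band(50, 300)), 50)
  expect_equal(endplate_thickness(rect_band(50, 300, scale = 2)), 100)
  # trapezoid: perpendicular extent grows linearly 40 -> 60 px
  m <- matrix(FALSE, 100, 340)
  for (x in 0:299) {
    h <- round(40 + 20 * x / 299)
    m[20 + seq_len(h), 20 + x + 1] <- TRUE
  }
  expect_equal(endplate_thickness(endplate_band(m)), 50, tolerance = 1)
})

test_that("branch crossings count straddling fascicles within the span", {
  tang <- line2d(c(0, 100), c(1, 0))
  p7 <- toy_pattern(sec_x = c(-75, -50, -25, 20, 45, 70, 90))
  expect_identical(branch_crossings(p7, tang), 7L)
  expect_identical(branch_crossings(toy_pattern(), tang), 0L)
  # a secondary crossing beyond the primary extremes is not counted
  nodes <- data.frame(id = 1:6,
                      x = c(0, -60, -50, -50, 55, 100),
                      y = c(0, 0, 0, 150, 0, 150))
  edges <- data.frame(parent = c(1L, 1L, 3L, 3L, 5L),
                      child = c(2L, 3L, 4L, 5L, 6L),
                      order = c(1L, 1L, 2L, 1L, 2L))
  p_out <- nerve_pattern(nodes, edges, entry = 1L)
  # vertical secondary at x = -50 crosses inside the span [-60, 55];
  # the slanted one crosses y = 80 at x = 55 + 45 * 80/150 = 79, outside
  expect_identical(branch_crossings(p_out, tang), 1L)
  # a pattern without a two-way primary split errors
  nodes <- data.frame(id = 1:2, x = c(0, 10), y = c(0, 0))
  edges <- data.frame(parent = 1L, child = 2L, order = 1L)
  single <- nerve_pattern(nodes, edges, entry = 1L)
  expect_error(branch_crossings(single, tang), class = "NoPrimarySplit")
  # gap tolerance merges close crossings
  p_close <- toy_pattern(sec_x = c(-50, 40, 41))
  expect_identical(branch_crossings(p_close, tang), 3L)
  expect_identical(branch_crossings(p_close, tang, gap_tolerance_um = 5), 2L)
})

test_that("split angle averages the first primary edges", {
  mk <- function(p1, p2) {
    nodes <- data.frame(id = 1:3,
                        x = c(0, p1[1], p2[1]), y = c(0, p1[2], p2[2]))
    edges <- data.frame(parent = c(1L, 1L), child = c(2L, 3L),
                        order = c(1L, 1L))
    nerve_pattern(nodes, edges, entry = 1L)
  }
  expect_equal(split_angle(mk(c(1, 0), c(-1, 0))), 180)
  expect_equal(split_angle(mk(c(1, 0), c(0, 1))), 90)
  expect_equal(split_angle(mk(c(1, 0), c(cos(150 * pi / 180),
                                         sin(150 * pi / 180)))), 150,
               tolerance = 1e-9)
})

test_that("morphometry is invariant under rigid motion and mirroring", {
  set.seed(42)
  for (i in 1:5) {
    par <- random_pattern_params()
    g <- make_nerve_pattern(par)
    ax <- fit_endplate_axis(g$band)
    d0 <- defasciculation_distance(g$pattern, ax)
    c0 <- branch_crossings(g$pattern, ax)
    a0 <- split_angle(g$pattern)
    R <- rotation_matrix(runif(1, 0, 360)); tr <- runif(2, -500, 500)
    pat_t <- transform_pattern(g$pattern, R, tr)
    ax_t <- transform_line(ax, R, tr)
    expect_equal(defasciculation_distance(pat_t, ax_t), d0,
                 tolerance = 1e-6)
    expect_identical(branch_crossings(pat_t, ax_t), c0)
    expect_equal(split_angle(pat_t), a0, tolerance = 1e-6)
    # mirror: reflect pattern and tangent across x = 0
    mir <- mirror_pattern(g$pattern)
    ax_m <- line2d(c(-ax$point[1], ax$point[2]),
                   c(ax$direction[1], -ax$direction[2]))
    expect_equal(defasciculation_distance(mir, ax_m), d0, tolerance = 1e-9)
    expect_identical(branch_crossings(mir, ax_m), c0)
    expect_equal(split_angle(mir), a0, tolerance = 1e-9)
  }
})

test_that("raster thickness is stable under image rotation", {
  band <- rect_band(50, 300, pad = 120)
  t0 <- endplate_thickness(band)
  img <- EBImage::rotate(EBImage::Image(band$mask * 1), 25)
  rot <- endplate_band(matrix(as.numeric(img) > 0.5, nrow(img), ncol(img)))
  expect_equal(endplate_thickness(rot), t0, tolerance = 0.02 * t0)
})

test_that("quantify_hemidiaphragm composes the four measures", {
  g <- make_nerve_pattern(preset_pattern_params("E15.5-left"))
  rec <- quantify_hemidiaphragm(g$pattern, g$band)
  ax <- fit_endplate_axis(g$band)
  expect_equal(rec$defasciculation_distance,
               defasciculation_distance(g$pattern, ax))
  expect_equal(rec$secondary_branch_count, branch_crossings(g$pattern, ax))
  expect_equal(rec$split_angle, split_angle(g$pattern))
  expect_equal(rec$endplate_thickness, endplate_thickness(g$band, axis = ax))
  # mirrored copy: identical record except the side label
  mir <- mirror_pattern(g$pattern)
  mir$nodes$x <- mir$nodes$x + 2 * g$truth$entry[1]  # back into the frame
  rec_m <- quantify_hemidiaphragm(mir, g$band)
  expect_identical(rec_m$side, "right")
  expect_equal(rec_m[-1], rec[-1], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("R/L ratio summaries report mean and SEM of per-pair ratios", {
  s <- lr_ratio_summary(data.frame(left = c(100, 100, 100),
                                   right = c(100, 100, 100)))
  expect_equal(s$mean, 1); expect_equal(s$sem, 0)
  s1 <- lr_ratio_summary(data.frame(left = 254.9, right = 529.3))
  expect_equal(round(s1$mean, 1), 2.1)
  expect_true(is.na(s1$sem))
  s3 <- lr_ratio_summary(data.frame(left = c(1, 2, 4), right = c(2, 6, 4)))
  expect_equal(s3$mean, 2)
  expect_equal(s3$sem, 0.577, tolerance = 1e-3)
  rm_ <- lr_ratio_summary(data.frame(left = c(1, 2, 4), right = c(2, 6, 4)),
                          aggregate = "ratio_of_means")
  expect_equal(rm_$mean, 12 / 7)
  expect_error(lr_ratio_summary(data.frame(left = 0, right = 1)),
               class = "ZeroDenominator")
})
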
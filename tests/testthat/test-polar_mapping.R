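test_that("reference point follows the view rule", {
  expect_equal(compute_reference_point(c(0, 0), c(4, 0), "2ch"), c(2, 0))
  # 4ch: midpoint displaced a quarter valve length towards the atrial side
  expect_equal(compute_reference_point(c(0, 0), c(4, 0), "4ch",
                                       la_side_hint = c(2, -5)), c(2, -1))
  expect_equal(compute_reference_point(c(0, 0), c(4, 0), "4ch",
                                       la_side_hint = c(2, 5)), c(2, 1))
  expect_error(compute_reference_point(c(1, 1), c(1, 1), "2ch"),
               "degenerate valve")
  expect_error(compute_reference_point(c(0, 0), c(4, 0), "4ch",
                                       la_side_hint = c(2, 0)), "collinear")
})

test_that("polar grid dimensions follow the sampling intervals", {
  frame <- matrix(7, 64, 64)
  p_s <- c(22, 32); p_e <- c(42, 32)   # valve length 20 px
  ref <- compute_reference_point(p_s, p_e, "2ch")
  po <- resample_polar(frame, p_s, p_e, ref, polar_grid_spec(),
                       la_side_hint = c(32, 12))
  expect_equal(po$n_r, 160L)           # 2 * 20 / 0.25
  expect_equal(po$n_theta, 180L)       # 180 deg / 1 deg
  # interpolating a constant gives a constant
  expect_true(all(abs(po$values - 7) < 1e-12))
})

test_that("column 0 points along the start ray and the last along the end ray", {
  frame <- matrix(0, 64, 64)
  p_s <- c(22, 32); p_e <- c(42, 32)
  ref <- c(32, 32)
  po <- resample_polar(frame, p_s, p_e, ref, polar_grid_spec(),
                       la_side_hint = c(32, 12))
  expect_equal(po$angles[1], atan2(p_s[2] - ref[2], p_s[1] - ref[1]))
  expect_equal(po$angles[po$n_theta] %% (2 * pi),
               atan2(p_e[2] - ref[2], p_e[1] - ref[1]) %% (2 * pi),
               tolerance = 1e-12)
  # the sweep passes through the atrial (upper, -y) half-plane
  mid_dir <- po$angles[90]
  expect_lt(sin(mid_dir), 0)
})

test_that("a centered disk maps to a constant-radius intensity step", {
  n <- 81
  cx <- 40
  xs <- matrix(0:(n - 1), n, n, byrow = TRUE); ys <- t(xs)
  rho <- 20
  frame <- ifelse((xs - cx)^2 + (ys - cx)^2 <= rho^2, 200, 0)
  p_s <- c(cx - 15, cx); p_e <- c(cx + 15, cx)
  po <- resample_polar(frame, p_s, p_e, c(cx, cx), polar_grid_spec(),
                       la_side_hint = c(cx, cx - 20))
  # per column the bright-to-dark step sits at rho, within the 1-pixel
  # quantization of the rasterized disk (axis-aligned boundary pixels)
  step_rows <- apply(po$values, 2, function(col) which(col < 100)[1] - 1L)
  expect_true(all(abs(step_rows - rho / 0.25) <= 1 / 0.25))
})

test_that("disk boundary round-trips to Cartesian within a pixel", {
  n <- 81; cx <- 40; rho <- 20
  xs <- matrix(0:(n - 1), n, n, byrow = TRUE); ys <- t(xs)
  frame <- ifelse((xs - cx)^2 + (ys - cx)^2 <= rho^2, 200, 0)
  p_s <- c(cx - 15, cx); p_e <- c(cx + 15, cx)
  po <- resample_polar(frame, p_s, p_e, c(cx, cx), polar_grid_spec(),
                       la_side_hint = c(cx, cx - 20))
  radii <- apply(po$values, 2, function(col) which(col < 100)[1] - 1L)
  poly <- contour_to_cartesian(radii, po)
  wall <- poly[seq_len(po$n_theta), ]
  d <- sqrt((wall[, 1] - cx)^2 + (wall[, 2] - cx)^2)
  expect_true(all(abs(d - rho) <= 1))
})

test_that("a constant contour lies at constant distance from the reference", {
  frame <- matrix(0, 64, 64)
  p_s <- c(22, 32); p_e <- c(42, 32)
  po <- resample_polar(frame, p_s, p_e, c(32, 32), polar_grid_spec(),
                       la_side_hint = c(32, 12))
  poly <- contour_to_cartesian(rep(80L, po$n_theta), po)
  wall <- poly[seq_len(po$n_theta), ]
  d <- sqrt((wall[, 1] - 32)^2 + (wall[, 2] - 32)^2)
  expect_equal(d, rep(80 * 0.25, po$n_theta), tolerance = 1e-9)
  expect_equal(unname(poly[po$n_theta + 1, ]), p_e)
  expect_equal(unname(poly[po$n_theta + 2, ]), p_s)
})

test_that("an all-zero contour collapses to the reference point", {
  frame <- matrix(0, 64, 64)
  p_s <- c(22, 32); p_e <- c(42, 32)
  po <- resample_polar(frame, p_s, p_e, c(32, 32), polar_grid_spec(),
                       la_side_hint = c(32, 12))
  poly <- contour_to_cartesian(rep(0L, po$n_theta), po)
  mask <- rasterize_polygon(poly, c(64, 64))
  expect_lte(sum(mask), 22)  # at most the rasterized chord sliver
})

test_that("each frame is resampled with its own valve points", {
  ph <- small_phantom_spec()
  v <- phantom_view(ph, "2ch")
  seg <- segment_cine(v$cine, v$annotation)
  # grids differ across frames because the valve length is modulated
  expect_gt(length(unique(seg$diagnostics$n_r)), 1L)
  # each chord equals that frame's annotation
  for (t in c(1L, 4L)) {
    expect_equal(seg$mv_chord[[t]][1, ], v$annotation$start[t, ],
                 tolerance = 1e-9)
  }
})
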
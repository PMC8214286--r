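test_that("internal energy matches direct evaluation", {
  expect_equal(internal_energy(rep(5, 10), snake_params(1, 1)), 0)
  expect_equal(internal_energy(c(0, 1, 2), snake_params(1, 0)), 2)
  expect_equal(internal_energy(c(0, 1, 2), snake_params(0, 1)), 0)
  expect_equal(internal_energy(c(0, 3, 1), snake_params(0.5, 2)),
               0.5 * (9 + 4) + 2 * (-0 + 6 - 1)^2)
  expect_error(internal_energy(c(1, 2), snake_params()), "at least 3")
})

test_that("image energy follows the weighted sweep discretization", {
  ic0 <- matrix(0, 4, 4)
  expect_equal(image_energy(c(0, 1, 2, 3), make_cost(ic0)), 0)
  # flat step on a uniform cost charges the plain pixel cost
  icc <- matrix(3, 4, 2)
  expect_equal(image_energy(c(2, 2), make_cost(icc)), 3)
  # a contour on zero-cost edge pixels with background 1 costs nothing
  ic <- matrix(1, 5, 4); ic[3, ] <- 0
  expect_equal(image_energy(rep(2L, 4), make_cost(ic)), 0)
})

test_that("energies match literal formula transcriptions on random cases", {
  set.seed(41)
  for (i in 1:50) {
    nr <- sample(3:8, 1); nt <- sample(3:8, 1)
    ic <- matrix(runif(nr * nt), nr, nt)
    f <- sample(0:(nr - 1), nt, replace = TRUE)
    a <- runif(1); b <- runif(1)
    expect_equal(internal_energy(f, snake_params(a, b)),
                 literal_internal_energy(f, a, b), tolerance = 1e-12)
    expect_equal(image_energy(f, make_cost(ic)),
                 literal_image_energy(f, ic), tolerance = 1e-12)
  }
})

test_that("a zero-cost row is the unique optimum when tips sit on it", {
  ic <- matrix(1, 10, 8); ic[4, ] <- 0
  co <- make_cost(ic)
  f <- optimize_contour(co, snake_params(0.5, 0.01), 3, 3)
  expect_equal(as.integer(f), rep(3L, 8))
  expect_equal(attr(f, "energy"), 0)
})

test_that("the optimizer equals exhaustive enumeration on small grids", {
  set.seed(42)
  for (i in 1:25) {
    nr <- sample(2:6, 1); nt <- sample(2:6, 1)
    ic <- matrix(runif(nr * nt), nr, nt)
    s <- sample(0:(nr - 1), 1); e <- sample(0:(nr - 1), 1)
    params <- snake_params(runif(1, 0, 0.1), runif(1, 0, 0.01))
    f <- optimize_contour(make_cost(ic), params, s, e)
    expect_equal(attr(f, "energy"),
                 brute_force_energy(ic, params$alpha, params$beta, s, e),
                 tolerance = 1e-10)
  }
})

test_that("with alpha = beta = 0 the optimum is the image-energy minimum", {
  set.seed(43)
  ic <- matrix(runif(5 * 5), 5, 5)
  f <- optimize_contour(make_cost(ic), snake_params(0, 0), 1, 3)
  expect_equal(attr(f, "energy"), brute_force_energy(ic, 0, 0, 1, 3),
               tolerance = 1e-10)
})

test_that("contour stretch decreases monotonically with elasticity", {
  set.seed(44)
  ic <- matrix(runif(12 * 10), 12, 10)
  co <- make_cost(ic)
  stretch <- sapply(c(0, 0.005, 0.02, 0.1, 1), function(a) {
    f <- optimize_contour(co, snake_params(a, 0), 2, 9)
    sum(diff(as.integer(f))^2)
  })
  expect_true(all(diff(stretch) <= 0))
})

test_that("the reported energy reproduces the energy of the returned contour", {
  set.seed(45)
  ic <- matrix(runif(20 * 15), 20, 15)
  co <- make_cost(ic)
  params <- snake_params()
  f <- optimize_contour(co, params, 5, 10)
  expect_equal(attr(f, "energy"),
               internal_energy(f, params) + image_energy(f, co),
               tolerance = 1e-10)
})

test_that("the banded search agrees with the full search away from the band", {
  set.seed(46)
  ic <- matrix(runif(30 * 20), 30, 20)
  co <- make_cost(ic)
  f_full <- optimize_contour(co, snake_params(), 10, 12, max_step = Inf)
  f_band <- optimize_contour(co, snake_params(), 10, 12, max_step = 29)
  expect_identical(as.integer(f_full), as.integer(f_band))
})

test_that("segment_frame recovers the phantom wall and is deterministic", {
  # noise-light, protrusion-free phantom: the wall profile is analytic
  sp <- phantom_spec(image_size = c(110L, 110L), frame_count = 2L,
                     radius_modulation = c(1, 1), mv_plane_motion = 0,
                     protrusions = list(), sigma_noise = 1, seed = 5L)
  v <- phantom_view(sp, "2ch")
  fr <- v$cine$frames[, , 1]
  f1 <- segment_frame(fr, v$annotation$start[1, ], v$annotation$end[1, ],
                      "2ch")
  f2 <- segment_frame(fr, v$annotation$start[1, ], v$annotation$end[1, ],
                      "2ch")
  expect_identical(as.integer(f1$contour), as.integer(f2$contour))
  # analytic wall radius per column, in rows (a, b in pixels; spacing 2 mm)
  a <- sp$mv_length / 2 / 2; b <- sp$base_radius / 2
  theta <- seq(pi, 0, length.out = f1$polar$n_theta)  # start ray at 180 deg
  truth_rows <- ellipse_wall_radius(theta, a, b) / 0.25
  err <- abs(as.integer(f1$contour) - truth_rows)
  expect_gte(mean(err <= 2), 0.95)
})

test_that("pure noise still yields a valid, flagged contour", {
  set.seed(47)
  fr <- matrix(rnorm(80 * 80, 100, 30), 80, 80)
  res <- segment_frame(fr, c(30, 40), c(50, 40), "2ch",
                       la_side_hint = c(40, 20))
  expect_length(res$contour, res$polar$n_theta)
  expect_true(is.logical(res$low_confidence))
  expect_true(all(res$contour >= 0 & res$contour < res$polar$n_r))
})
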
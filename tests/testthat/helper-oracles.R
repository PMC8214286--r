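# Independent oracles and shared fixtures for the test suite.

# wrap a bare matrix as a cost image
make_cost <- function(values, edges = NULL) {
  structure(list(values = values,
                 edges = edges %||% (values == min(values)),
                 n_r = nrow(values), n_theta = ncol(values),
                 delta_r = 0.25),
            class = "cost_image")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Literal transcription of the discretized internal energy: a sum of
# alpha-weighted squared first differences over consecutive columns plus
# beta-weighted squared second differences over interior columns. Written
# as an explicit loop, independently of the package's vectorized version.
literal_internal_energy <- function(f, alpha, beta) {
  n <- length(f)
  e <- 0
  for (i in 1:(n - 1)) e <- e + alpha * (f[i] - f[i + 1])^2
  if (n >= 3) for (i in 2:(n - 1))
    e <- e + beta * (-f[i - 1] + 2 * f[i] - f[i + 1])^2
  e
}

# Literal transcription of the discretized image energy: for consecutive
# columns, sweep j from f_{i-1} to f_i with weights |f_i - j| / (d + 1)
# on column i-1 and |j - f_{i-1}| / (d + 1) on column i. Flat steps
# (d = 0) charge the plain pixel cost, the package's documented rule.
literal_image_energy <- function(f, ic) {
  e <- 0
  for (i in 2:length(f)) {
    a <- f[i - 1]; b <- f[i]
    d <- abs(a - b)
    if (d == 0) {
      e <- e + ic[b + 1, i]
    } else {
      step <- if (b >= a) 1 else -1
      for (j in seq(a, b, by = step))
        e <- e + (abs(b - j) / (d + 1)) * ic[j + 1, i - 1] +
                 (abs(j - a) / (d + 1)) * ic[j + 1, i]
    }
  }
  e
}

# exhaustive minimum-energy contour with fixed tips (tiny grids only)
brute_force_energy <- function(ic, alpha, beta, row_start, row_end) {
  nr <- nrow(ic); nt <- ncol(ic)
  stopifnot(nr <= 6, nt <= 6)
  interior <- nt - 2
  best <- Inf
  combos <- if (interior > 0)
    as.matrix(do.call(expand.grid, rep(list(0:(nr - 1)), interior)))
  else matrix(0, 1, 0)
  for (i in seq_len(nrow(combos))) {
    f <- unname(c(row_start, as.numeric(combos[i, ]), row_end))
    e <- literal_image_energy(f, ic)
    if (length(f) >= 3) e <- e + literal_internal_energy(f, alpha, beta)
    else e <- e + alpha * (f[1] - f[2])^2
    if (e < best) best <- e
  }
  best
}

# analytic wall radius (pixels, from the chord midpoint) of the phantom's
# half-ellipse at atrial-side angle theta (radians from the chord)
ellipse_wall_radius <- function(theta, a, b) {
  a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
}

# session-cached default phantom (shared by the heavier tests)
phantom_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- lacine::phantom_generate(phantom_spec())
    cache
  }
})

# a small, fast phantom for smoke tests
small_phantom_spec <- function(frames = 6L, seed = 11L)
  phantom_spec(image_size = c(96L, 96L), frame_count = frames, seed = seed)
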
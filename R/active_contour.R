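# Discrete active contour on the polar grid. The contour is a function
# radius = f(angle), one radius per column, and the optimum of
# internal (elasticity + rigidity) energy plus accumulated image cost is
# found exactly by dynamic programming over (column, row, previous row)
# states — the shortest path through a layered graph.

#' Snake energy weights
#'
#' @param alpha elasticity weight, penalizing first differences of the
#'   contour (default 0.02).
#' @param beta rigidity weight, penalizing second differences
#'   (default 0.0002).
#' @return A list of class `snake_params`.
#' @export
snake_params <- function(alpha = 0.02, beta = 0.0002) {
  .assert(alpha >= 0 && beta >= 0, "alpha and beta must be non-negative")
  structure(list(alpha = alpha, beta = beta), class = "snake_params")
}

#' Internal (elasticity + rigidity) energy of a contour
#'
#' Discretized as `sum alpha * (f_j - f_{j+1})^2` over consecutive column
#' pairs plus `sum beta * (-f_{j-1} + 2 f_j - f_{j+1})^2` over interior
#' columns, the summations running over the angular index.
#'
#' @param contour numeric vector of radial indices, length >= 3.
#' @param params a [snake_params()].
#' @return Non-negative scalar.
#' @export
internal_energy <- function(contour, params = snake_params()) {
  f <- as.numeric(contour)
  .assert(length(f) >= 3L, "contour must have at least 3 columns")
  d1 <- diff(f)
  inner <- 2:(length(f) - 1L)
  d2 <- -f[inner - 1L] + 2 * f[inner] - f[inner + 1L]
  params$alpha * sum(d1^2) + params$beta * sum(d2^2)
}

#' Image energy of a contour on a cost surface
#'
#' For each consecutive column pair the cost is accumulated along the
#' vertical sweep between the two radii, with linear weights
#' `|f_i - j| / (|f_{i-1} - f_i| + 1)` on the previous column and
#' `|j - f_{i-1}| / (|f_{i-1} - f_i| + 1)` on the current one. When the two
#' radii are equal the sweep's weights vanish identically; to avoid flat
#' segments riding free, the plain cost of the current pixel is charged
#' instead (a documented deviation from the literal discretization).
#'
#' @param contour integer radial indices (0-based), one per cost column.
#' @param cost a [canny_cost()] result or any list with a `values` matrix.
#' @return Non-negative scalar.
#' @export
image_energy <- function(contour, cost) {
  ic <- cost$values
  f <- as.integer(round(contour))
  .assert(length(f) == ncol(ic), "contour length must match cost width")
  .assert(all(f >= 0 & f <= nrow(ic) - 1L), "contour radius out of range")
  total <- 0
  for (i in seq_len(length(f) - 1L)) {
    a <- f[i]; b <- f[i + 1L]
    d <- abs(a - b)
    if (d == 0L) {
      total <- total + ic[b + 1L, i + 1L]
    } else {
      js <- a:b
      total <- total + sum(abs(b - js) * ic[js + 1L, i] +
                           abs(js - a) * ic[js + 1L, i + 1L]) / (d + 1)
    }
  }
  total
}

#' Globally optimal contour through a cost image
#'
#' Finds the single-valued contour with fixed end rows minimizing
#' [internal_energy()] plus [image_energy()], by exact dynamic programming
#' over states augmented with the predecessor row (so the rigidity term is
#' a valid step cost). Ties are broken deterministically towards smaller
#' rows. `max_step` optionally bounds the radial jump between adjacent
#' columns, shrinking the search; the default is unrestricted.
#'
#' @param cost a [canny_cost()] result.
#' @param params a [snake_params()].
#' @param row_start,row_end 0-based tip rows in the first and last column,
#'   e.g. from [snap_tips()].
#' @param max_step maximum |f_j - f_{j+1}| allowed, or `Inf`.
#' @return Integer vector of 0-based radii with attribute `energy`, the
#'   minimal total energy.
#' @export
optimize_contour <- function(cost, params = snake_params(), row_start,
                             row_end, max_step = Inf) {
  .assert(row_start >= 0 && row_start <= cost$n_r - 1 &&
          row_end >= 0 && row_end <= cost$n_r - 1,
          "contour tips must lie inside the radial range")
  ms <- if (is.finite(max_step)) as.integer(max_step) else -1L
  res <- dp_optimize_cpp(cost$values, params$alpha, params$beta,
                         as.integer(row_start), as.integer(row_end), ms)
  structure(as.integer(res$path), energy = res$energy)
}

#' Segment a single frame
#'
#' Composes the per-frame pipeline: blood-pool threshold, clipping,
#' reference point, polar resampling, Canny cost image, tip snapping, and
#' the dynamic-programming contour. The returned contour is flagged
#' low-confidence when fewer than 10% of its pixels lie on detected edges.
#'
#' @param frame numeric H x W matrix.
#' @param p_start,p_end valve points for this frame.
#' @param view `"2ch"` or `"4ch"`.
#' @param config configuration list, see [la_config()].
#' @param threshold optional precomputed clipping threshold (used when the
#'   whole cine shares one threshold).
#' @param la_side_hint optional point on the atrial side; derived
#'   automatically when `config$polar$la_side == "auto"`.
#' @return A list: `contour` (with `energy` attribute), `polar`, `cost`,
#'   `tips`, `threshold`, `low_confidence`, `edge_fraction`.
#' @export
segment_frame <- function(frame, p_start, p_end, view = c("2ch", "4ch"),
                          config = la_config(), threshold = NULL,
                          la_side_hint = NULL) {
  view <- match.arg(view)
  if (is.null(threshold))
    threshold <- compute_threshold(frame, tol = config$gmm$tol,
                                   max_iter = config$gmm$max_iter,
                                   seed = config$gmm$seed)$threshold
  clipped <- clip_above(frame, threshold)
  if (is.null(la_side_hint))
    la_side_hint <- switch(config$polar$la_side,
      auto = auto_la_side_hint(frame, p_start, p_end, threshold),
      up = (p_start + p_end) / 2 + c(0, -1) * .vnorm(p_end - p_start),
      down = (p_start + p_end) / 2 + c(0, 1) * .vnorm(p_end - p_start),
      stop("polar.la_side must be auto, up or down"))
  ref <- compute_reference_point(p_start, p_end, view, la_side_hint)
  span <- if (view == "2ch") config$polar$angular_span_2ch
          else config$polar$angular_span_4ch
  spec <- polar_grid_spec(delta_r = config$polar$delta_r,
                          delta_theta = config$polar$delta_theta,
                          angular_span = span,
                          radial_factor = config$polar$radial_factor)
  polar <- resample_polar(clipped, p_start, p_end, ref, spec, la_side_hint)
  cost <- canny_cost(polar, sigma = config$canny$sigma,
                     low_frac = config$canny$low_frac,
                     high_frac = config$canny$high_frac,
                     edge_cost = config$canny$edge_cost,
                     bg_cost = config$canny$bg_cost)
  tips <- snap_tips(cost, polar$mv_rows[1], polar$mv_rows[2])
  contour <- optimize_contour(cost, snake_params(config$snake$alpha,
                                                 config$snake$beta),
                              tips[1], tips[2],
                              max_step = config$snake$max_step)
  on_edge <- cost$edges[cbind(contour + 1L, seq_along(contour))]
  edge_fraction <- mean(on_edge)
  list(contour = contour, polar = polar, cost = cost, tips = tips,
       threshold = threshold, low_confidence = edge_fraction < 0.10,
       edge_fraction = edge_fraction)
}

#' Automatic atrial-side hint
#'
#' Locates the atrial blood pool relative to the valve line: among
#' supra-threshold pixels within 1.5 valve lengths of the valve midpoint,
#' the side of the valve line carrying the greater bright-pixel mass is
#' taken as atrial, and the centroid of its bright pixels is returned.
#'
#' @param frame numeric matrix (original, unclipped intensities).
#' @param p_start,p_end valve points.
#' @param threshold blood-pool threshold.
#' @return Numeric (x, y) hint point.
#' @export
auto_la_side_hint <- function(frame, p_start, p_end, threshold) {
  mid <- (as.numeric(p_start) + as.numeric(p_end)) / 2
  L <- .vnorm(as.numeric(p_end) - as.numeric(p_start))
  n <- .unit(.perp(as.numeric(p_end) - as.numeric(p_start)))
  idx <- which(frame >= threshold, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("cannot determine atrial side: no bright pixels")
  pts <- cbind(idx[, 2] - 1, idx[, 1] - 1)  # (x, y)
  rel <- sweep(pts, 2, mid)
  near <- sqrt(rowSums(rel^2)) <= 1.5 * L
  .assert(any(near), "cannot determine atrial side: no bright pixels near the valve")
  proj <- rel[near, , drop = FALSE] %*% n
  up_mass <- sum(proj > 0); down_mass <- sum(proj < 0)
  .assert(up_mass != down_mass || up_mass > 0,
          "cannot determine atrial side: bright mass is balanced")
  side <- if (up_mass >= down_mass) proj > 0 else proj < 0
  colMeans(pts[near, , drop = FALSE][side, , drop = FALSE])
}
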
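# Mitral-valve-anchored polar resampling. Rays fan out from a reference
# point on the valve chord; under this reparametrization the atrial wall
# becomes a single-valued function of angle and the pulmonary-vein /
# appendage openings are superimposed by wall on either side.

#' Polar grid specification
#'
#' @param delta_r radial step in Cartesian pixels (default 0.25).
#' @param delta_theta angular step in degrees (default 1).
#' @param angular_span nominal sweep in degrees: 180 for the 2-chamber view,
#'   233 for the 4-chamber view. Sets the number of columns only; columns
#'   are spread uniformly over the angle actually subtended by the two
#'   valve-point rays on the atrial side.
#' @param radial_factor radial range as a multiple of the valve length
#'   (default 2).
#' @return A list of class `polar_grid_spec`.
#' @export
polar_grid_spec <- function(delta_r = 0.25, delta_theta = 1,
                            angular_span = 180, radial_factor = 2) {
  .assert(delta_r > 0 && delta_theta > 0 && radial_factor > 0,
          "polar grid steps must be positive")
  .assert(angular_span > 0 && angular_span <= 360,
          "angular_span must be in (0, 360]")
  structure(list(delta_r = delta_r, delta_theta = delta_theta,
                 angular_span = angular_span, radial_factor = radial_factor),
            class = "polar_grid_spec")
}

#' Per-frame polar reference point
#'
#' The 2-chamber reference point is the midpoint of the two valve points.
#' In the 4-chamber view, whose atrium is elongated and curvilinear, the
#' midpoint is displaced perpendicular to the valve chord, a quarter of the
#' chord length into the atrial half-plane.
#'
#' @param p_start,p_end valve points (x, y) in pixels; `p_start` is the
#'   anterior (2ch) or lateral (4ch) point.
#' @param view `"2ch"` or `"4ch"`.
#' @param la_side_hint any point known to lie on the atrial side of the
#'   valve line; required for `"4ch"`.
#' @return Numeric (x, y) reference point.
#' @export
compute_reference_point <- function(p_start, p_end, view = c("2ch", "4ch"),
                                    la_side_hint = NULL) {
  view <- match.arg(view)
  p_start <- as.numeric(p_start); p_end <- as.numeric(p_end)
  L <- .vnorm(p_end - p_start)
  if (L == 0) stop("degenerate valve: coincident MV points")
  mid <- (p_start + p_end) / 2
  if (view == "2ch") return(mid)
  .assert(!is.null(la_side_hint), "4ch reference point needs an la_side_hint")
  n <- .unit(.perp(p_end - p_start))
  side <- sum((as.numeric(la_side_hint) - mid) * n)
  if (side == 0) stop("la_side_hint is collinear with the MV line")
  mid + sign(side) * n * L / 4
}

#' Resample a frame onto the valve-anchored polar grid
#'
#' Column j's ray direction interpolates uniformly from the
#' reference-to-`p_start` direction (column 0) to the reference-to-`p_end`
#' direction (last column), sweeping through the atrial half-plane. Samples
#' are taken every `delta_r` pixels along each ray by bilinear
#' interpolation; positions outside the image take the nearest border value.
#'
#' @param frame numeric H x W matrix.
#' @param p_start,p_end valve points (x, y) in pixels.
#' @param ref_point polar origin, from [compute_reference_point()].
#' @param spec a [polar_grid_spec()].
#' @param la_side_hint point on the atrial side of the valve line, used to
#'   pick the sweep direction. May be omitted when `ref_point` is off the
#'   valve line (4ch), in which case the displacement itself marks the side.
#' @return An object of class `polar_image`: `values` (N_r x N_theta),
#'   `angles` (per-column ray directions, radians), `ref_point`, `p_start`,
#'   `p_end`, `delta_r`, `delta_theta`, `theta_start`, `theta_end`, `sweep`
#'   (signed subtended angle), `mv_rows` (fractional radial indices of the
#'   valve points in the first and last column), `n_r`, `n_theta`.
#' @export
resample_polar <- function(frame, p_start, p_end, ref_point,
                           spec = polar_grid_spec(), la_side_hint = NULL) {
  p_start <- as.numeric(p_start); p_end <- as.numeric(p_end)
  ref_point <- as.numeric(ref_point)
  L <- .vnorm(p_end - p_start)
  if (L == 0) stop("degenerate valve: coincident MV points")
  n_r <- as.integer(round(spec$radial_factor * L / spec$delta_r))
  n_theta <- as.integer(round(spec$angular_span / spec$delta_theta))
  .assert(n_r >= 2L && n_theta >= 2L, "polar grid must be at least 2 x 2")

  v_start <- p_start - ref_point
  v_end <- p_end - ref_point
  .assert(.vnorm(v_start) > 0 && .vnorm(v_end) > 0,
          "reference point coincides with a valve point")
  a_start <- atan2(v_start[2], v_start[1])
  a_end <- atan2(v_end[2], v_end[1])
  mid <- (p_start + p_end) / 2
  hint_vec <- if (!is.null(la_side_hint)) as.numeric(la_side_hint) - ref_point
              else if (.vnorm(ref_point - mid) > 1e-9 * L) ref_point - mid
              else stop("la_side_hint required: reference point lies on the MV line")
  a_hint <- atan2(hint_vec[2], hint_vec[1])
  two_pi <- 2 * pi
  d_ccw <- (a_end - a_start) %% two_pi
  t_hint <- (a_hint - a_start) %% two_pi
  sweep <- if (t_hint <= d_ccw) d_ccw else -(two_pi - d_ccw)
  angles <- a_start + sweep * (0:(n_theta - 1L)) / (n_theta - 1L)

  h <- nrow(frame); w <- ncol(frame)
  radii <- (0:(n_r - 1L)) * spec$delta_r
  x <- ref_point[1] + outer(radii, cos(angles))
  y <- ref_point[2] + outer(radii, sin(angles))
  # clamp-to-border sampling
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0; fy <- y - y0
  at <- function(yy, xx) matrix(frame[cbind(as.vector(yy) + 1L,
                                            as.vector(xx) + 1L)],
                                n_r, n_theta)
  vals <- (1 - fx) * (1 - fy) * at(y0, x0) + fx * (1 - fy) * at(y0, x1) +
          (1 - fx) * fy * at(y1, x0) + fx * fy * at(y1, x1)

  structure(list(values = vals, angles = angles, ref_point = ref_point,
                 p_start = p_start, p_end = p_end,
                 delta_r = spec$delta_r, delta_theta = spec$delta_theta,
                 theta_start = a_start, theta_end = angles[n_theta],
                 sweep = sweep,
                 mv_rows = c(.vnorm(v_start), .vnorm(v_end)) / spec$delta_r,
                 n_r = n_r, n_theta = n_theta),
            class = "polar_image")
}

#' Map a polar contour back to a closed Cartesian polygon
#'
#' Each column's radial index becomes a distance from the reference point
#' along that column's ray; the polygon is closed by appending the valve
#' end and start points, producing the D-shape cut flat at the mitral valve.
#'
#' @param contour integer radial indices, one per polar column (0-based).
#' @param polar the [resample_polar()] output the contour lives on.
#' @return An (N_theta + 2) x 2 matrix of (x, y) vertices.
#' @export
contour_to_cartesian <- function(contour, polar) {
  radii <- as.numeric(contour)
  .assert(length(radii) == polar$n_theta,
          "contour length must match the polar grid's column count")
  r <- radii * polar$delta_r
  wall <- cbind(polar$ref_point[1] + r * cos(polar$angles),
                polar$ref_point[2] + r * sin(polar$angles))
  rbind(wall, polar$p_end, polar$p_start)
}
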
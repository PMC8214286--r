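# Canny edge detection on the polar grid, recast as a cost surface for the
# shortest-path contour: detected edge pixels are cheap (cost 0), everything
# else expensive (cost 1), so minimizing accumulated cost follows the wall.

.sobel_col <- cbind(c(-1, -2, -1), c(0, 0, 0), c(1, 2, 1))
.sobel_row <- rbind(c(-1, -2, -1), c(0, 0, 0), c(1, 2, 1))

#' Canny edge map of a matrix
#'
#' Classic Canny: Gaussian smoothing, Sobel gradients, non-maximum
#' suppression along the quantized gradient direction, and hysteresis with
#' thresholds expressed as fractions of the maximum gradient magnitude
#' (which makes the edge set invariant to affine intensity rescaling).
#' Hysteresis keeps every weak-threshold connected component that contains a
#' strong pixel (connectivity as in [EBImage::bwlabel()]).
#'
#' @param img numeric matrix.
#' @param sigma Gaussian smoothing scale in grid pixels.
#' @param low_frac,high_frac hysteresis thresholds as fractions of the
#'   maximum gradient magnitude, `0 < low_frac < high_frac <= 1`.
#' @return Logical matrix of edge pixels (all `FALSE` for a constant image).
#' @export
canny_edges <- function(img, sigma = 2, low_frac = 0.1, high_frac = 0.2) {
  .assert(low_frac > 0 && low_frac < high_frac && high_frac <= 1,
          "need 0 < low_frac < high_frac <= 1")
  img <- unclass(img)
  rg <- diff(range(img))
  if (rg == 0) return(matrix(FALSE, nrow(img), ncol(img)))
  if (sigma > 0) {
    size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
    size <- min(size, 2L * (min(dim(img)) %/% 2L) - 1L)
    if (size >= 3L) {
      brush <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
      img <- EBImage::filter2(img, brush, boundary = "replicate")
    }
  }
  gc_ <- EBImage::filter2(img, .sobel_col, boundary = "replicate")
  gr_ <- EBImage::filter2(img, .sobel_row, boundary = "replicate")
  mag <- sqrt(gc_^2 + gr_^2)
  mx <- max(mag)
  nr <- nrow(img); nc <- ncol(img)
  # guard against FFT ripple on (near-)flat images
  if (mx <= 1e-8 * rg) return(matrix(FALSE, nr, nc))

  # non-maximum suppression: compare against the two neighbours along the
  # gradient direction, quantized to 4 orientations
  ang <- atan2(gr_, gc_) %% pi
  q <- as.integer(floor(((ang + pi / 8) %% pi) / (pi / 4))) %% 4L
  # q: 0 -> across columns, 1 -> diagonal (+1,+1), 2 -> across rows,
  #    3 -> diagonal (-1,+1) in (row, col) offsets
  dr <- c(0L, 1L, 1L, -1L)[q + 1L]
  dc <- c(1L, 1L, 0L, 1L)[q + 1L]
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mag
  n_fwd <- pad[cbind(as.vector(rows + dr) + 1L, as.vector(cols + dc) + 1L)]
  n_bwd <- pad[cbind(as.vector(rows - dr) + 1L, as.vector(cols - dc) + 1L)]
  keep <- mag > matrix(n_bwd, nr, nc) & mag >= matrix(n_fwd, nr, nc)
  thin <- ifelse(keep, mag, 0)

  strong <- thin >= high_frac * mx
  weak <- thin >= low_frac * mx
  if (!any(strong)) return(matrix(FALSE, nr, nc))
  lab <- EBImage::bwlabel(weak)
  good <- unique(lab[strong])
  weak & (matrix(lab %in% good, nr, nc))
}

#' Cost image from a polar image
#'
#' Runs [canny_edges()] on the polar-resampled intensities and encodes the
#' result as a cost surface: `edge_cost` (default 0) on edges, `bg_cost`
#' (default 1) elsewhere. A constant polar image yields no edges and an
#' all-`bg_cost` surface, which is valid input for the optimizer.
#'
#' @param polar a [resample_polar()] result.
#' @param sigma,low_frac,high_frac Canny parameters, see [canny_edges()].
#'   `sigma` defaults to 2 polar rows (0.5 Cartesian pixels at the default
#'   radial step).
#' @param edge_cost,bg_cost cost assigned to edge / non-edge pixels.
#' @return An object of class `cost_image`: `values` (N_r x N_theta,
#'   non-negative), logical `edges`, and the grid geometry carried over.
#' @export
canny_cost <- function(polar, sigma = 2, low_frac = 0.1, high_frac = 0.2,
                       edge_cost = 0, bg_cost = 1) {
  .assert(edge_cost >= 0 && bg_cost >= 0, "costs must be non-negative")
  edges <- canny_edges(polar$values, sigma = sigma, low_frac = low_frac,
                       high_frac = high_frac)
  values <- matrix(bg_cost, nrow(edges), ncol(edges))
  values[edges] <- edge_cost
  structure(list(values = values, edges = edges, n_r = polar$n_r,
                 n_theta = polar$n_theta, delta_r = polar$delta_r),
            class = "cost_image")
}

#' Snap contour tips to the nearest edge pixels
#'
#' The valve points do not always coincide with the detected myocardial
#' edge; the contour tips are therefore the edge pixels in the first and
#' last polar column nearest to the valve points' radial positions. Ties go
#' to the smaller radius; a column without edges falls back to the valve
#' row itself.
#'
#' @param cost a [canny_cost()] result.
#' @param mv_row_start,mv_row_end fractional radial indices of the valve
#'   points in columns 0 and N_theta - 1 (see `mv_rows` of
#'   [resample_polar()]).
#' @return Integer vector `c(row_start, row_end)` of 0-based radial indices.
#' @export
snap_tips <- function(cost, mv_row_start, mv_row_end) {
  one <- function(col_edges, mv_row) {
    rows <- which(col_edges) - 1L
    fallback <- min(max(as.integer(round(mv_row)), 0L), cost$n_r - 1L)
    if (length(rows) == 0L) return(fallback)
    d <- abs(rows - mv_row)
    rows[which.min(d)]  # rows ascending: first minimum = smaller radius
  }
  c(one(cost$edges[, 1], mv_row_start),
    one(cost$edges[, ncol(cost$edges)], mv_row_end))
}
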
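# Temporal and angular post-processing. The atrium in the polar grid is a
# single dominant "V": spurious secondary peaks (pulmonary vein / appendage
# openings the edge detector latched onto) are excised per frame, then the
# stacked contour matrix F(theta, t) is median-smoothed across angle and
# time before the final Cartesian masks are rasterized.

#' Remove non-predominant peaks from a contour
#'
#' The contour's dominant apex — the local maximum widest at half its
#' prominence, which is robust against one-column spikes overtopping the
#' true roof — is preserved. Every other local maximum whose prominence
#' exceeds `prominence_frac * (max - min)` of the contour is excised:
#' radii between its nearest flanking local minima are replaced by the
#' pointwise minimum of the original values and the straight line joining
#' those minima. No radius ever increases.
#'
#' @param contour numeric vector of radial indices.
#' @param prominence_frac prominence threshold as a fraction of the
#'   contour's radial range, in (0, 1).
#' @return Vector of the same length and type.
#' @export
filter_peaks <- function(contour, prominence_frac = 0.15) {
  .assert(prominence_frac > 0 && prominence_frac < 1,
          "prominence_frac must be in (0, 1)")
  f <- as.numeric(contour)
  n <- length(f)
  rng <- max(f) - min(f)
  if (rng == 0 || n < 3L) return(contour)

  # local maxima with plateau runs collapsed to their first index
  peaks <- integer(0)
  j <- 1L
  while (j <= n) {
    k <- j
    while (k < n && f[k + 1L] == f[j]) k <- k + 1L
    left_ok <- j == 1L || f[j - 1L] < f[j]
    right_ok <- k == n || f[k + 1L] < f[j]
    if (left_ok && right_ok && !(j == 1L && k == n)) peaks <- c(peaks, j)
    j <- k + 1L
  }
  if (length(peaks) <= 1L) return(contour)

  # standard prominence: minimum between the peak and the nearest strictly
  # higher sample on each side (contour end if none)
  prominence_of <- function(p) {
    hl <- which(f[seq_len(p - 1L)] > f[p])
    lo <- if (length(hl)) max(hl) else 1L
    hr <- which(f[(p + 1L):n] > f[p]) + p
    hi <- if (length(hr)) min(hr) else n
    f[p] - max(min(f[lo:p]), min(f[p:hi]))
  }
  proms <- vapply(peaks, prominence_of, numeric(1))
  # the dominant apex is the peak widest at half prominence, not the
  # tallest sample: a one-column spike can overtop the true apex
  widths <- vapply(seq_along(peaks), function(k) {
    level <- f[peaks[k]] - proms[k] / 2
    l <- peaks[k]; while (l > 1L && f[l - 1L] >= level) l <- l - 1L
    r <- peaks[k]; while (r < n && f[r + 1L] >= level) r <- r + 1L
    r - l + 1L
  }, integer(1))
  dominant <- peaks[order(-widths, -f[peaks])[1]]

  out <- f
  for (k in seq_along(peaks)) {
    p <- peaks[k]
    if (p == dominant || proms[k] <= prominence_frac * rng) next
    # excision interval: the prominence base on each side (minimum between
    # the peak and the nearest strictly higher sample, contour end if none)
    hl <- which(f[seq_len(p - 1L)] > f[p])
    lo <- if (length(hl)) max(hl) else 1L
    hr <- which(f[(p + 1L):n] > f[p]) + p
    hi <- if (length(hr)) min(hr) else n
    a <- lo + which.min(f[lo:p]) - 1L
    b <- p + which.min(f[p:hi]) - 1L
    # a peak overtopping the dominant apex would sweep across it; stop at
    # the deepest saddle between the peak and the apex instead
    if (a <= dominant && dominant <= b) {
      if (dominant < p) a <- dominant + which.min(f[dominant:p]) - 1L
      else b <- p + which.min(f[p:dominant]) - 1L
    }
    seg <- a:b
    line <- f[a] + (f[b] - f[a]) * (seg - a) / max(b - a, 1L)
    out[seg] <- pmin(out[seg], line)
  }
  # the dominant apex is never altered
  out[dominant] <- f[dominant]
  if (is.integer(contour)) out <- as.integer(round(out))
  out
}

# rectangular 2-D median filter with replicated edges (no installed package
# offers a non-square kernel with replication on plain matrices)
.median_filter2 <- function(mat, k_row, k_col) {
  .assert(k_row %% 2L == 1L && k_col %% 2L == 1L,
          "median kernel dimensions must be odd")
  .assert(k_row <= nrow(mat) && k_col <= ncol(mat),
          "median kernel larger than the matrix")
  nr <- nrow(mat); nc <- ncol(mat)
  hr <- k_row %/% 2L; hc <- k_col %/% 2L
  pad <- mat[pmin(pmax(seq_len(nr + 2L * hr) - hr, 1L), nr),
             pmin(pmax(seq_len(nc + 2L * hc) - hc, 1L), nc), drop = FALSE]
  stack <- array(NA_real_, c(nr, nc, k_row * k_col))
  k <- 0L
  for (dr in 0:(k_row - 1L)) for (dc in 0:(k_col - 1L)) {
    k <- k + 1L
    stack[, , k] <- pad[dr + seq_len(nr), dc + seq_len(nc)]
  }
  apply(stack, c(1, 2), stats::median)
}

# centered running mean across columns with replicated edges; removes the
# radial-grid quantization jitter of the integer contours before the
# polygons are measured (arc lengths of jagged curves are biased long)
.runmean_theta <- function(mat, k) {
  if (k <= 1L) return(mat)
  nc <- ncol(mat)
  hc <- k %/% 2L
  pad <- mat[, pmin(pmax(seq_len(nc + 2L * hc) - hc, 1L), nc), drop = FALSE]
  out <- matrix(0, nrow(mat), nc)
  for (d in 0:(k - 1L)) out <- out + pad[, d + seq_len(nc), drop = FALSE]
  out / k
}

#' Median-smooth the stacked contour matrix
#'
#' The per-frame contours stacked as a T x N_theta matrix (frames in rows,
#' angles in columns) are smoothed with a rectangular median filter with
#' replicated edges. Radii should be supplied in physical units (radius
#' index times the radial step) so frames with different radial ranges are
#' commensurable; see [segment_cine()].
#'
#' @param stack numeric T x N_theta matrix.
#' @param kernel `c(k_time, k_theta)`, both odd.
#' @return Smoothed matrix of the same shape.
#' @export
smooth_stack <- function(stack, kernel = c(3L, 5L)) {
  .median_filter2(stack, as.integer(kernel[1]), as.integer(kernel[2]))
}

#' Rasterize a closed polygon into a binary mask
#'
#' Even-odd scanline fill at pixel centers; pixels whose center lies on the
#' polygon boundary are included. Self-intersecting inputs are filled under
#' the even-odd rule.
#'
#' @param polygon n x 2 matrix of (x, y) vertices (closed implicitly).
#' @param image_shape `c(H, W)`.
#' @return Integer H x W matrix of 0/1.
#' @export
rasterize_polygon <- function(polygon, image_shape) {
  rasterize_polygon_cpp(as.numeric(polygon[, 1]), as.numeric(polygon[, 2]),
                        as.integer(image_shape[1]),
                        as.integer(image_shape[2]))
}

#' Build Cartesian masks from smoothed contours
#'
#' Maps each frame's contour to its D-shaped polygon (closed across the
#' valve chord) and rasterizes it.
#'
#' @param contours list of T radial-index vectors.
#' @param polars list of T [resample_polar()] results (frame-matched).
#' @param image_shape `c(H, W)`.
#' @param diagnostics optional diagnostics to carry in the result.
#' @return An [la_segmentation()].
#' @export
build_masks <- function(contours, polars, image_shape, diagnostics = list()) {
  t_n <- length(contours)
  .assert(length(polars) == t_n, "one polar image per contour required")
  polys <- vector("list", t_n); masks <- vector("list", t_n)
  chords <- vector("list", t_n)
  for (t in seq_len(t_n)) {
    polys[[t]] <- contour_to_cartesian(contours[[t]], polars[[t]])
    masks[[t]] <- rasterize_polygon(polys[[t]], image_shape)
    chords[[t]] <- rbind(polars[[t]]$p_start, polars[[t]]$p_end)
  }
  la_segmentation(masks, polys, chords, diagnostics)
}

#' Segment a whole cine
#'
#' Runs [segment_frame()] on every frame (the reference point and polar
#' grid follow that frame's valve points), filters spurious peaks per
#' frame, median-smooths the stacked contour matrix in physical radius
#' units, and rasterizes the final D-shaped masks.
#'
#' @param cine a [cine_sequence()].
#' @param annotation an [mv_annotation()] with matching frame count.
#' @param config configuration list, see [la_config()].
#' @return An [la_segmentation()] whose `diagnostics` carry per-frame
#'   thresholds, energies, edge fractions, grid sizes, and the contour
#'   stack before/after smoothing.
#' @export
segment_cine <- function(cine, annotation, config = la_config()) {
  t_n <- cine$frame_count
  .assert(annotation$frame_count == t_n,
          "annotation and cine disagree on frame count")
  thresholds <- if (config$gmm$per_frame) {
    vapply(seq_len(t_n), function(t)
      compute_threshold(cine$frames[, , t], tol = config$gmm$tol,
                        max_iter = config$gmm$max_iter,
                        seed = config$gmm$seed)$threshold, numeric(1))
  } else {
    rep(compute_threshold(cine$frames[, , 1], tol = config$gmm$tol,
                          max_iter = config$gmm$max_iter,
                          seed = config$gmm$seed)$threshold, t_n)
  }
  # the atrial side is anatomy, constant over the cycle: decide it once by
  # majority vote of the per-frame bright-mass rule (robust to single-frame
  # flips when the ventricular pool rivals the atrial one)
  hints <- vector("list", t_n)
  if (config$polar$la_side == "auto") {
    side <- vapply(seq_len(t_n), function(t) {
      p_s <- annotation$start[t, ]; p_e <- annotation$end[t, ]
      h <- auto_la_side_hint(cine$frames[, , t], p_s, p_e, thresholds[t])
      sign(sum((h - (p_s + p_e) / 2) * .perp(p_e - p_s)))
    }, numeric(1))
    la_sign <- if (sum(side) >= 0) 1 else -1
    hints <- lapply(seq_len(t_n), function(t) {
      p_s <- annotation$start[t, ]; p_e <- annotation$end[t, ]
      (p_s + p_e) / 2 + la_sign * .unit(.perp(p_e - p_s)) * .vnorm(p_e - p_s)
    })
  }
  frames_out <- vector("list", t_n)
  for (t in seq_len(t_n)) {
    frames_out[[t]] <- segment_frame(cine$frames[, , t],
                                     annotation$start[t, ],
                                     annotation$end[t, ],
                                     view = cine$view, config = config,
                                     threshold = thresholds[t],
                                     la_side_hint = hints[[t]])
  }
  polars <- lapply(frames_out, `[[`, "polar")
  raw <- lapply(frames_out, function(fr)
    filter_peaks(fr$contour, config$post$prominence_frac))
  # stack in physical units (radius index * delta_r, Cartesian pixels)
  phys <- do.call(rbind, lapply(seq_len(t_n), function(t)
    as.numeric(raw[[t]]) * polars[[t]]$delta_r))
  kt <- min(config$post$kernel_time, if (t_n %% 2L == 1L) t_n else t_n - 1L)
  smoothed <- smooth_stack(phys, kernel = c(kt, config$post$kernel_theta))
  # sub-grid angular smoothing: the median output still carries the
  # radial-grid quantization of the discrete contours, which would bias
  # the perimeter (and hence strain) long
  averaged <- .runmean_theta(smoothed, config$post$mean_theta)
  final <- lapply(seq_len(t_n), function(t) {
    r <- averaged[t, ] / polars[[t]]$delta_r
    pmin(pmax(r, 0), polars[[t]]$n_r - 1)
  })
  diagnostics <- list(
    threshold = vapply(frames_out, `[[`, numeric(1), "threshold"),
    energy = vapply(frames_out, function(fr)
      attr(fr$contour, "energy"), numeric(1)),
    edge_fraction = vapply(frames_out, `[[`, numeric(1), "edge_fraction"),
    low_confidence = vapply(frames_out, `[[`, logical(1), "low_confidence"),
    n_r = vapply(polars, `[[`, integer(1), "n_r"),
    n_theta = vapply(polars, `[[`, integer(1), "n_theta"),
    stack_raw = phys, stack_smoothed = smoothed)
  build_masks(final, polars, dim(cine$frames)[1:2], diagnostics)
}
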
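# Segmentation agreement metrics in physical units: Dice overlap of masks,
# and mean / Hausdorff contour distances between boundary point sets.

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks are defined to agree (1).
#'
#' @param a,b binary masks of identical shape.
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(a, b) {
  .assert(all(dim(a) == dim(b)), "masks must share a shape")
  a <- a != 0; b <- b != 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Boundary pixel centers of a mask
#'
#' A mask pixel is boundary if any of its 8 neighbours (or the image
#' border) is background.
#'
#' @param mask binary matrix.
#' @return n x 2 matrix of (x, y) pixel-center coordinates.
#' @export
mask_boundary <- function(mask) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  interior <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    interior <- interior & pad[2:(nr + 1L) + dr, 2:(nc + 1L) + dc]
  }
  idx <- which(m & !interior, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
}

.points_mm <- function(pts, spacing) {
  cbind(pts[, 1] * spacing[2], pts[, 2] * spacing[1])
}

.directed_nn <- function(a_mm, b_mm) {
  d2 <- outer(a_mm[, 1], b_mm[, 1], "-")^2 +
        outer(a_mm[, 2], b_mm[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}

#' Mean contour distance (mm)
#'
#' Symmetric mean of the two directed mean nearest-neighbour distances
#' between two contour point sets.
#'
#' @param a,b n x 2 matrices of (x, y) pixel points (e.g. from
#'   [mask_boundary()]), both non-empty.
#' @param spacing `c(dy, dx)` in mm/pixel.
#' @return Distance in mm.
#' @export
mean_contour_distance <- function(a, b, spacing) {
  a <- rbind(a); b <- rbind(b)
  .assert(nrow(a) > 0 && nrow(b) > 0, "contours must be non-empty")
  am <- .points_mm(a, spacing); bm <- .points_mm(b, spacing)
  (mean(.directed_nn(am, bm)) + mean(.directed_nn(bm, am))) / 2
}

#' Hausdorff distance (mm)
#'
#' Maximum over both directed maximal nearest-neighbour distances.
#'
#' @inheritParams mean_contour_distance
#' @return Distance in mm.
#' @export
hausdorff <- function(a, b, spacing) {
  a <- rbind(a); b <- rbind(b)
  .assert(nrow(a) > 0 && nrow(b) > 0, "contours must be non-empty")
  am <- .points_mm(a, spacing); bm <- .points_mm(b, spacing)
  max(max(.directed_nn(am, bm)), max(.directed_nn(bm, am)))
}

#' Per-frame segmentation agreement table
#'
#' Dice, mean contour distance and Hausdorff distance between predicted and
#' reference mask stacks, frame by frame, with a mean +/- SD summary
#' attached as the `"summary"` attribute.
#'
#' @param pred,ref H x W x T binary arrays (or [la_segmentation()] objects).
#' @param spacing `c(dy, dx)` in mm/pixel.
#' @return `data.frame(frame, dice, mcd_mm, hd_mm)`.
#' @export
evaluate_segmentation <- function(pred, ref, spacing) {
  if (inherits(pred, "la_segmentation")) pred <- pred$masks
  if (inherits(ref, "la_segmentation")) ref <- ref$masks
  if (length(dim(pred)) == 2L) dim(pred) <- c(dim(pred), 1L)
  if (length(dim(ref)) == 2L) dim(ref) <- c(dim(ref), 1L)
  .assert(all(dim(pred) == dim(ref)), "mask stacks must share a shape")
  t_n <- dim(pred)[3]
  res <- data.frame(frame = seq_len(t_n) - 1L, dice = NA_real_,
                    mcd_mm = NA_real_, hd_mm = NA_real_)
  for (t in seq_len(t_n)) {
    pa <- pred[, , t]; rb <- ref[, , t]
    res$dice[t] <- dice(pa, rb)
    ba <- mask_boundary(pa); bb <- mask_boundary(rb)
    if (nrow(ba) > 0 && nrow(bb) > 0) {
      res$mcd_mm[t] <- mean_contour_distance(ba, bb, spacing)
      res$hd_mm[t] <- hausdorff(ba, bb, spacing)
    }
  }
  summary_df <- data.frame(
    metric = c("dice", "mcd_mm", "hd_mm"),
    mean = c(mean(res$dice), mean(res$mcd_mm), mean(res$hd_mm)),
    sd = c(stats::sd(res$dice), stats::sd(res$mcd_mm), stats::sd(res$hd_mm)))
  attr(res, "summary") <- summary_df
  res
}
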
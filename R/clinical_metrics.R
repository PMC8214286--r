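# Clinical layer: biplane area-length volumes across the cycle, atrial
# ejection fraction (EDV = minimal, ESV = maximal volume — the atrial
# convention), and perimeter-based longitudinal strain referenced to the
# first frame. All quantities are computed in millimetres via the pixel
# spacing; the first frame (index 0 here) is the strain reference.

#' Atrial long-axis length (mm)
#'
#' Distance from the mitral-valve midpoint to the superior aspect of the
#' atrium, measured along the direction perpendicular to the valve chord:
#' the maximal perpendicular projection of the polygon vertices, on the
#' atrial side.
#'
#' @param polygon n x 2 matrix of (x, y) pixel vertices.
#' @param mv_pair 2 x 2 matrix, rows = valve start and end points (pixels).
#' @param spacing `c(dy, dx)` mm/pixel.
#' @return Length in mm (>= 0).
#' @export
la_length <- function(polygon, mv_pair, spacing) {
  .assert(nrow(polygon) >= 3L, "degenerate polygon")
  to_mm <- function(p) cbind(p[, 1] * spacing[2], p[, 2] * spacing[1])
  poly <- to_mm(rbind(polygon)); mv <- to_mm(rbind(mv_pair))
  mid <- colMeans(mv)
  n <- .unit(.perp(mv[2, ] - mv[1, ]))
  proj <- sweep(poly, 2, mid) %*% n
  max(max(proj), max(-proj))  # atrial side = side of the farthest vertex
}

#' Biplane area-length volume (ml)
#'
#' `Volume = (16 / (3 pi)) * Area_2ch * Area_4ch / (Length_2ch +
#' Length_4ch)`, with areas in mm^2, lengths in mm, converted to ml. For a
#' disk of radius R in both views (areas `pi R^2`, lengths `2R`) this is
#' exactly the sphere volume `(4/3) pi R^3`.
#'
#' @param area_2ch,area_4ch view areas in mm^2.
#' @param len_2ch,len_4ch view lengths in mm.
#' @return Volume in ml.
#' @export
biplane_volume <- function(area_2ch, area_4ch, len_2ch, len_4ch) {
  if (area_2ch == 0 || area_4ch == 0) return(0)
  .assert(len_2ch + len_4ch > 0, "zero total length with non-zero area")
  (16 / (3 * pi)) * area_2ch * area_4ch / (len_2ch + len_4ch) / 1000
}

.frame_area_mm2 <- function(mask, spacing) sum(mask != 0) * prod(spacing)

# polygon arc length excluding the valve chord: the closing edge between
# the last two vertices (p_end -> p_start) is the chord
.perimeter_excl_mv <- function(polygon, spacing) {
  poly <- cbind(polygon[, 1] * spacing[2], polygon[, 2] * spacing[1])
  n <- nrow(poly)
  edges <- sqrt(rowSums((poly[c(2:n, 1), ] - poly)^2))
  sum(edges) - edges[n - 1L]
}

#' Biplane volume curve with EDV, ESV and EF
#'
#' Per-frame biplane volumes from paired two- and four-chamber
#' segmentations (mask pixel count times pixel area; lengths from
#' [la_length()]), with EDV = minimal volume, ESV = maximal volume, and
#' `EF = 100 * (ESV - EDV) / ESV`.
#'
#' @param seg_2ch,seg_4ch [la_segmentation()] objects with equal frame
#'   counts.
#' @param spacing_2ch,spacing_4ch per-view `c(dy, dx)` mm/pixel.
#' @return List: `volume_ml` (length T), `edv`, `esv`, `ef`.
#' @export
volume_curve <- function(seg_2ch, seg_4ch, spacing_2ch, spacing_4ch) {
  t_n <- seg_2ch$frame_count
  .assert(seg_4ch$frame_count == t_n, "views disagree on frame count")
  vols <- vapply(seq_len(t_n), function(t) {
    a2 <- .frame_area_mm2(seg_2ch$masks[, , t], spacing_2ch)
    a4 <- .frame_area_mm2(seg_4ch$masks[, , t], spacing_4ch)
    if (a2 == 0 || a4 == 0) return(0)
    l2 <- la_length(seg_2ch$contours[[t]], seg_2ch$mv_chord[[t]], spacing_2ch)
    l4 <- la_length(seg_4ch$contours[[t]], seg_4ch$mv_chord[[t]], spacing_4ch)
    biplane_volume(a2, a4, l2, l4)
  }, numeric(1))
  esv <- max(vols); edv <- min(vols)
  if (esv == 0) stop("ejection fraction undefined: all volumes are zero")
  list(volume_ml = vols, edv = edv, esv = esv,
       ef = 100 * (esv - edv) / esv)
}

#' Longitudinal strain curve with GLS
#'
#' `Strain_t = 100 * ((P2_t + P4_t) / (P2_0 + P4_0) - 1)` where each P is
#' the polygon arc length excluding the valve chord; the global
#' longitudinal strain is the curve's maximum. The first frame is the
#' reference, so `strain[1] == 0` exactly.
#'
#' @inheritParams volume_curve
#' @return List: `strain_pct` (length T), `gls`.
#' @export
strain_curve <- function(seg_2ch, seg_4ch, spacing_2ch, spacing_4ch) {
  t_n <- seg_2ch$frame_count
  .assert(seg_4ch$frame_count == t_n, "views disagree on frame count")
  p2 <- vapply(seg_2ch$contours, .perimeter_excl_mv, numeric(1),
               spacing = spacing_2ch)
  p4 <- vapply(seg_4ch$contours, .perimeter_excl_mv, numeric(1),
               spacing = spacing_4ch)
  .assert(p2[1] + p4[1] > 0, "zero initial perimeter")
  strain <- 100 * ((p2 + p4) / (p2[1] + p4[1]) - 1)
  list(strain_pct = strain, gls = max(strain))
}

#' Full clinical metrics from a biplane segmentation pair
#'
#' @inheritParams volume_curve
#' @return Object of class `la_clinical`: `volume_ml`, `strain_pct`,
#'   `edv`, `esv`, `ef`, `gls`.
#' @export
clinical_metrics <- function(seg_2ch, seg_4ch, spacing_2ch, spacing_4ch) {
  vc <- volume_curve(seg_2ch, seg_4ch, spacing_2ch, spacing_4ch)
  sc <- strain_curve(seg_2ch, seg_4ch, spacing_2ch, spacing_4ch)
  structure(c(vc, sc), class = "la_clinical")
}

#' @export
print.la_clinical <- function(x, ...) {
  cat(sprintf("LA clinical metrics: EDV %.1f ml, ESV %.1f ml, EF %.1f%%, GLS %.1f%%\n",
              x$edv, x$esv, x$ef, x$gls))
  invisible(x)
}
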
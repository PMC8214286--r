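# a 1-frame segmentation holding an axis-aligned rectangle, chord at the
# bottom edge; handy because every clinical quantity has a closed form
rect_seg <- function(x0, y0, wpx, hpx, shape = c(40, 40)) {
  poly <- rbind(c(x0, y0 + hpx), c(x0, y0), c(x0 + wpx, y0),
                c(x0 + wpx, y0 + hpx),            # wall
                c(x0 + wpx, y0 + hpx), c(x0, y0 + hpx))  # p_end, p_start
  mask <- rasterize_polygon(poly, shape)
  la_segmentation(array(mask, c(shape, 1)), list(poly),
                  list(rbind(c(x0, y0 + hpx), c(x0 + wpx, y0 + hpx))))
}

test_that("the area-length volume reproduces the sphere exactly", {
  for (R in c(1, 10, 37.5)) {
    v <- biplane_volume(pi * R^2, pi * R^2, 2 * R, 2 * R)
    expect_equal(v, (4 / 3) * pi * R^3 / 1000, tolerance = 1e-14)
  }
  expect_equal(biplane_volume(0, 100, 10, 10), 0)
  expect_equal(biplane_volume(200, 200, 10, 10),
               4 * biplane_volume(100, 100, 10, 10))
  expect_error(biplane_volume(10, 10, 0, 0), "zero total length")
})

test_that("atrial length is the perpendicular reach from the valve midpoint", {
  # half-disk of radius R about the valve midpoint
  ang <- seq(pi, 0, length.out = 51)   # includes pi/2 exactly
  R <- 15
  poly <- rbind(cbind(20 + R * cos(ang), 20 - R * sin(ang)),
                c(20 + R, 20), c(20 - R, 20))
  mv <- rbind(c(20 - R, 20), c(20 + R, 20))
  expect_equal(la_length(poly, mv, c(1, 1)), R, tolerance = 1e-6)
  expect_equal(la_length(poly, mv, c(2, 2)), 2 * R, tolerance = 1e-6)
  # collapsed onto the chord -> zero length
  flat <- rbind(c(5, 20), c(15, 20), c(10, 20))
  expect_equal(la_length(flat, mv, c(1, 1)), 0)
})

test_that("atrial length is invariant to rigid rotation of the scene", {
  ang <- seq(pi, 0, length.out = 51)
  R <- 12
  rot <- function(p, phi) cbind(p[, 1] * cos(phi) - p[, 2] * sin(phi),
                                p[, 1] * sin(phi) + p[, 2] * cos(phi))
  poly <- rbind(cbind(R * cos(ang), -R * sin(ang)), c(R, 0), c(-R, 0))
  mv <- rbind(c(-R, 0), c(R, 0))
  for (phi in c(0.3, 1.2, 2.5))
    expect_equal(la_length(rot(poly, phi), rot(mv, phi), c(1, 1)), R,
                 tolerance = 1e-6)
})

test_that("volume curve and ejection fraction follow the biplane formula", {
  # rectangle 10 x 8 px at 1 mm: area 80 mm^2, length 8 mm (chord on top)
  s_small <- rect_seg(5, 5, 10, 8)
  s_big <- rect_seg(5, 5, 14, 10)    # area 140+, length 10
  two <- function(a, b) la_segmentation(
    array(c(a$masks, b$masks), c(40, 40, 2)),
    c(a$contours, b$contours), c(a$mv_chord, b$mv_chord))
  seg2 <- two(s_small, s_big); seg4 <- two(s_small, s_big)
  vc <- volume_curve(seg2, seg4, c(1, 1), c(1, 1))
  a1 <- sum(s_small$masks); a2 <- sum(s_big$masks)
  v1 <- (16 / (3 * pi)) * a1 * a1 / 16 / 1000
  v2 <- (16 / (3 * pi)) * a2 * a2 / 20 / 1000
  expect_equal(vc$volume_ml, c(v1, v2), tolerance = 1e-12)
  expect_equal(vc$edv, min(v1, v2))
  expect_equal(vc$esv, max(v1, v2))
  expect_equal(vc$ef, 100 * (v2 - v1) / v2, tolerance = 1e-12)
  # constant curve -> zero ejection fraction
  segc <- two(s_small, s_small)
  expect_equal(volume_curve(segc, segc, c(1, 1), c(1, 1))$ef, 0)
})

test_that("strain is the perimeter change versus the first frame", {
  s1 <- rect_seg(5, 5, 10, 8)
  scale_seg <- function(s, k) {
    poly <- (s$contours[[1]] - 20) * k + 20
    mask <- rasterize_polygon(poly, c(40, 40))
    la_segmentation(array(mask, c(40, 40, 1)), list(poly),
                    list((s$mv_chord[[1]] - 20) * k + 20))
  }
  s2 <- scale_seg(s1, 1.3)
  two <- function(a, b) la_segmentation(
    array(c(a$masks, b$masks), c(40, 40, 2)),
    c(a$contours, b$contours), c(a$mv_chord, b$mv_chord))
  sc <- strain_curve(two(s1, s2), two(s1, s2), c(1, 1), c(1, 1))
  expect_equal(sc$strain_pct[1], 0)
  expect_equal(sc$strain_pct[2], 30, tolerance = 1e-9)
  expect_equal(sc$gls, 30, tolerance = 1e-9)
  # time-constant contours give identically zero strain
  scc <- strain_curve(two(s1, s1), two(s1, s1), c(1, 1), c(1, 1))
  expect_true(all(scc$strain_pct == 0))
  expect_equal(scc$gls, 0)
})

test_that("EF and GLS are invariant to in-plane translation", {
  s1 <- rect_seg(5, 5, 10, 8); s2 <- rect_seg(5, 5, 14, 10)
  shift_seg <- function(s, d) la_segmentation(
    array(rasterize_polygon(s$contours[[1]] + d, c(40, 40)), c(40, 40, 1)),
    list(s$contours[[1]] + d), list(s$mv_chord[[1]] + d))
  two <- function(a, b) la_segmentation(
    array(c(a$masks, b$masks), c(40, 40, 2)),
    c(a$contours, b$contours), c(a$mv_chord, b$mv_chord))
  cm0 <- clinical_metrics(two(s1, s2), two(s1, s2), c(1, 1), c(1, 1))
  cm1 <- clinical_metrics(two(shift_seg(s1, 3), shift_seg(s2, 3)),
                          two(s1, s2), c(1, 1), c(1, 1))
  expect_equal(cm1$ef, cm0$ef, tolerance = 1e-9)
  expect_equal(cm1$gls, cm0$gls, tolerance = 1e-9)
})

test_that("single-frame input yields length-1 curves and zero EF", {
  s1 <- rect_seg(5, 5, 10, 8)
  cm <- clinical_metrics(s1, s1, c(1, 1), c(1, 1))
  expect_length(cm$volume_ml, 1)
  expect_equal(cm$ef, 0)
  expect_equal(cm$strain_pct, 0)
})
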
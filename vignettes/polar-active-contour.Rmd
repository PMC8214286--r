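---
title: "Polar active contours for time-resolved left atrial segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polar active contours for time-resolved left atrial segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lacine)
```

## The problem and the model

The left atrium (LA) in long-axis cine MRI must be delineated in every
time frame to measure phasic volumes and strain. Three boundary
segments make this hard for generic methods: the pulmonary-vein ostia
and the appendage are open connections to the bright blood pool, and
the mitral-valve (MV) plane — the flat cut separating the atrium from
the ventricle — moves through the cycle and often has no intensity edge
at all (ventricular blood is just as bright).

`lacine` treats the wall as a *discrete active contour on a polar
grid*. Two tracked MV insertion points per frame (an input to this
package) anchor a fan of rays from a reference point on the valve
chord; in that reparametrization the wall is a single-valued function
$r = f(\theta)$, the valve cut is simply the segment between the two
anchor rays, and the vein/appendage openings project as narrow radial
peaks that post-processing can excise. The contour minimizes

$$E(f) \;=\; \sum_{j} \alpha\,(f_j - f_{j+1})^2
      \;+\; \sum_{j} \beta\,(-f_{j-1} + 2f_j - f_{j+1})^2
      \;+\; E_\mathrm{im}(f, I_c),$$

where $I_c$ is a binary cost image from Canny edge detection (edges
cost 0, background 1 — minimizing accumulated cost therefore *attracts*
the contour to edges), $\alpha$ penalizes stretch and $\beta$
curvature. $E_\mathrm{im}$ accumulates, for each pair of consecutive
columns, the cost along the vertical sweep between the two radii with
linear weights $|f_i - j|/(d+1)$ and $|j - f_{i-1}|/(d+1)$,
$d = |f_{i-1} - f_i|$. Because $f$ is single-valued in $\theta$, the
minimization is a shortest-path problem and is solved *globally* —
no initialization, no local minima.

## Pipeline stages and their tunables

**Blood-pool clipping.** Each frame's intensities are modelled as a
two-component Gaussian mixture (myocardium / blood) fitted by EM:
median-split initialization, variance floor $10^{-6}\,\mathrm{range}^2$,
relative log-likelihood tolerance $10^{-6}$, at most 200 iterations
(`gmm.*`). All pixels above the bright mean are clipped to it, so no
edge survives inside the pool. The threshold is refit per frame by
default (`gmm.per_frame`) because bSSFP intensities drift over the
cycle; a single shared threshold is one switch away.

**Polar resampling.** The reference point is the MV midpoint in 2ch; in
4ch it is displaced perpendicularly into the atrium by a quarter of the
valve length, which captures that view's elongated, curved shape — the
two valve-point rays then subtend $\approx 233^\circ$ on the atrial
side. Sampling steps are $\Delta r = 0.25$ px and
$\Delta\theta = 1^\circ$; the radial range is twice the valve length
(so grids have roughly 130–200 rows), and the nominal angular spans
(180° / 233°, `polar.angular_span_*`) set the column count while the
columns themselves are spread uniformly over the angle actually
subtended, guaranteeing that the first and last column pass exactly
through the valve points. Interpolation is bilinear with
clamp-to-border so image edges do not fabricate gradients. The atrial
side of the valve line is decided automatically: per frame, the side
carrying more supra-threshold mass within 1.5 valve lengths of the
midpoint votes, and the majority across frames wins — anatomy does not
flip mid-cycle, and the vote protects against single frames where the
ventricular pool rivals the atrial one (`polar.la_side` overrides).

**Edge cost.** Canny with $\sigma = 2$ polar rows (half a Cartesian
pixel radially), hysteresis thresholds at 10% / 20% of the maximum
gradient (`canny.*`). Fractional thresholds make the edge set invariant
to affine intensity rescaling. Contour tips snap to the edge pixels
nearest each valve point in the terminal columns (ties toward smaller
radius; the valve row itself if a column has no edge) — necessary
because the annular points rarely sit exactly on the myocardial edge.

**Optimizer.** $\alpha = 0.02$, $\beta = 0.0002$ (`snake.*`). States
are (column, row, previous row) so the second-difference term is a
valid step cost; the state graph is a forward-layered DAG, so a single
column sweep of relaxations finds the same global optimum a best-first
(Dijkstra-style) search would, with simpler bookkeeping. Two devices
keep the exact search fast: pair image-energy terms are evaluated in
O(1) from per-column prefix sums of $I_c$ and $j \cdot I_c$, and the
minimization over the predecessor row of
$\mathrm{dp} + \beta\,(a - K)^2$ for all needed $K$ uses the lower
envelope of parabolas (the 1-D quadratic distance transform), making a
full frame a few tens of milliseconds. The pipeline additionally bounds
the radial jump between adjacent 1° columns at `snake.max_step` = 24
rows (6 px): with $\alpha = 0.02$ a larger jump costs more internal
energy than any plausible image-cost saving, and wall radius varies
smoothly with angle except at the excluded openings. `optimize_contour`
itself defaults to the unrestricted search, which the test suite holds
against exhaustive enumeration.

**Degenerate sweep.** The printed discretization of $E_\mathrm{im}$
assigns *zero* cost to flat steps ($f_{i-1} = f_i$ makes both weights
0), which would let a constant contour cross any cost field for free.
The implementation charges the plain pixel cost $I_c(i, f_i)$ in that
case — the smallest change that restores coherence — and both the
energy functions and the optimizer use the same rule.

**Peak filtering.** "Non-predominant" peaks are defined by prominence:
any local maximum other than the dominant apex whose prominence exceeds
`post.prominence_frac` (default 0.15) of the contour's radial range is
excised, bridging its prominence-base interval with a straight chord
taken pointwise-min with the original radii (so no radius ever grows).
The *dominant apex* is the peak widest at half its prominence rather
than the tallest sample: a one-column spike can overtop the true roof,
and height alone would then protect exactly the artifact that should be
removed. An excision never crosses the dominant apex; it stops at the
deepest saddle towards it.

**Temporal smoothing.** The per-frame contours are stacked as
$F(\theta, t)$ in physical radius units (frames differ in radial range
because the annulus moves) and median-filtered with a 3-frame × 5°
kernel, edge-replicated — the smallest kernel that repairs
single-frame or single-angle outliers (`post.kernel_*`). A 5-column
running mean (`post.mean_theta`) is then applied and the final polygons
use the resulting sub-grid radii: the integer contours carry
$\pm1$-row quantization jitter which biases polygon arc length — and
therefore strain — several percent long, while sub-grid radii remove
the bias without affecting mask overlap.

**Clinical layer.** Areas are mask pixel counts times the pixel area;
the atrial length is the farthest polygon vertex measured along the
perpendicular to the valve chord from its midpoint (the literal
"perpendicular line" reading, rather than the absolute farthest
vertex); perimeters are polygon arc lengths excluding the chord —
pixelated boundary lengths overestimate by up to $\sqrt2$ on diagonals,
and strain is a ratio of perimeters. EDV and ESV are the minimum and
maximum of the biplane volume curve (atrial convention), the first
frame is the strain reference, and distance metrics symmetrize the
directed means (the averaging convention; Hausdorff takes the max).
Masks are closed regions, so the valve chord participates in the
contour distance metrics — a comparability caveat when matching against
conventions that drop it.

## The phantom: what it emulates, and what it does not

The phantom generates the study conditions the pipeline targets:
30-frame cines at $2\times2$ mm with a D-shaped atrium — a half-ellipse
capped by the valve chord, semi-axis along the chord equal to half the
32 mm valve length, height 45 mm (elongated, as real atria are) — with
everything scaled by a reservoir-like waveform
$1 + 0.3\sin(\pi t/(T-1))$. Scaling the whole shape (the annulus
contracts with the atrium) gives analytic truth EF
$= (1 - 1.3^{-3}) \cdot 100 \approx 54.4\%$ and truth GLS exactly 30%,
both inside reported patient ranges. The valve plane translates 6 mm
towards the ventricle at mid-cycle. Blood (mean 200) and muscle
(mean 60) get Gaussian noise (SD 12), a bright ventricular pool sits
below the chord so that *no* edge exists at the valve plane (tip
snapping and the D-cut must do the work), and bright stubs — one
appendage in 2ch, two pulmonary veins in 4ch — are contiguous with the
cavity but excluded from the truth mask. Truth areas, lengths and
perimeters are closed-form (the half-ellipse arc by quadrature), so
recovery errors are exact.

Valve-point perturbations emulate inter-observer placement variability:
each point is displaced in a uniformly random direction by a magnitude
drawn from $\mathcal N(1.5, 0.7^2)$ mm truncated at zero (the
distribution behind the reported mean ± SD is not identified further;
a per-axis normal variant is selectable).

What the phantom does *not* model: off-resonance banding and flow
artifacts, trabeculated texture, through-plane motion, anisotropic
noise, or ostia immediately adjacent to the atrial roof — stubs there
merge with the apex in the polar profile and are not excludable by any
peak rule (the 4ch stubs sit at 40°/140° from the chord for this
reason). Passing phantom tests therefore demonstrates the geometric and
numerical machinery, not clinical-grade robustness on patient images.

## Numerical choices and degenerate inputs

Ties in the optimizer resolve towards smaller rows, deterministically;
repeated runs are bit-identical (the only randomness anywhere is the
phantom's noise and the perturbation draws, both seeded). A constant
polar image yields an all-background cost surface, which is valid
optimizer input; a frame of pure noise still returns a contour, flagged
low-confidence when fewer than 10% of its pixels lie on detected
edges. All-identical intensities are a hard error for the mixture fit
("degenerate intensity distribution"); a single outlier pixel is
absorbed by the variance floor and leaves the threshold near the
background level. Coincident valve points are rejected everywhere.
Rasterization is even-odd scanline at pixel centers with a small
epsilon so on-boundary centers are included; a chord lying exactly on a
row of pixel centers is a knife-edge case in which that row's
membership follows the half-open scanline rule.

## Problem sizes used by the shipped tests

The test suite and the acceptance script run the full default phantom
(both views, 30 frames each), 20 perturbation re-segmentations of it,
brute-force contour enumeration on grids up to $6 \times 6$, and
1000-case formula cross-checks; the whole suite completes in about
three minutes on a single CPU, the acceptance script in under two.

## Known limitations

* MV insertion points are required input; their upstream generation is
  out of scope.
* The 4ch angular span is fixed at 233° by the offset-reference
  geometry; strongly atypical 4ch anatomy may subtend a different
  angle, and the span is configurable for that reason.
* The banded optimizer is exact only within its jump bound; pathological
  cost fields demanding >6 px jumps between adjacent degree columns
  would need `snake.max_step = Inf`.
* Strain inherits any perimeter bias from residual protrusion
  inclusion; on the phantom this stays within ~2 points of truth, but
  ostia near the roof would degrade it.
* Clinical metrics assume paired views with equal frame counts and
  in-plane spacing per view; no through-plane (slice thickness) term is
  used anywhere — the biplane formula is the standard 2-D surrogate.
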
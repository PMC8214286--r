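# lacine

Automated, time-resolved segmentation of the **left atrium (LA)** in
2-chamber and 4-chamber cardiac MRI long-axis cine images, with the
derived clinical measurements — biplane volumes, ejection fraction and
longitudinal strain — and a synthetic phantom test bed with analytic
ground truth.

LA size and function are established imaging biomarkers for atrial
fibrillation, stroke risk and diastolic dysfunction, but delineating the
atrium in every frame of a cine by hand is slow and observer-dependent.
The atrium is also an awkward target for generic segmentation: it is
small, thin-walled, and its boundary is interrupted by the pulmonary-vein
(PV) ostia, the left atrial appendage (LAA), and a mitral-valve (MV)
plane that moves through the cycle and all but disappears in diastole.

## Method

Given a cine stack and the two MV insertion points per frame (these are
an *input* — produced upstream by feature tracking or a landmark
network), each frame passes through four stages:

1. **Preprocessing.** The frame's intensity histogram is modelled as a
   two-component Gaussian mixture (myocardium low, blood high) fitted by
   EM; every pixel above the bright component's mean &mu;<sub>high</sub> is clipped
   to it, flattening the blood pool so no spurious edges survive inside
   it.
2. **Polar mapping.** A reference point is placed on the valve chord —
   the MV midpoint in 2ch, displaced perpendicularly into the atrium by a
   quarter chord length in 4ch — and the image is bilinearly resampled
   onto a fan of rays (&theta;, r): &Delta;r = 0.25 px, &Delta;&theta; = 1°, radial
   range twice the valve length, angular span 180° (2ch) or 233° (4ch)
   between the two valve-point rays. In this geometry the atrial wall is
   a single-valued function r = f(&theta;) and the PV/LAA openings project as
   narrow peaks.
3. **Edge detection and contour reconstruction.** Canny edge detection
   on the polar image yields a binary cost image I<sub>c</sub> (edges cost 0,
   background 1). The contour f minimizing

   E(f) = &Sigma;<sub>j</sub> &alpha;(f<sub>j</sub> − f<sub>j+1</sub>)² + &Sigma;<sub>j</sub> &beta;(−f<sub>j−1</sub> + 2f<sub>j</sub> − f<sub>j+1</sub>)² + E<sub>im</sub>(f, I<sub>c</sub>)

   with &alpha; = 0.02 (elasticity), &beta; = 0.0002 (rigidity) and E<sub>im</sub> the
   linearly weighted cost accumulated between consecutive columns, is
   found *exactly* by shortest-path dynamic programming over states
   (column, row, previous row); the contour tips are the edge pixels
   nearest the valve points in the first and last column.
4. **Post-processing and Cartesian mapping.** Non-predominant peaks
   (the PV/LAA projections) are excised per frame, the stacked contour
   matrix F(&theta;, t) is median-filtered over angle and time, and each
   contour is mapped back to a D-shaped polygon closed flat across the
   valve chord, then rasterized to a mask.

From paired 2ch + 4ch segmentations the package computes the biplane
area–length volume

Volume = (16 / 3&pi;) · A<sub>2ch</sub> A<sub>4ch</sub> / (L<sub>2ch</sub> + L<sub>4ch</sub>),

the volume curve's extrema (EDV = minimum, ESV = maximum — atrial
convention), EF = (ESV − EDV)/ESV, and longitudinal strain as the
relative change of the combined wall perimeters (MV chord excluded)
versus the first frame, with GLS its maximum. Agreement utilities
provide Dice, mean contour distance and Hausdorff distance in mm.

## Worked example

No patient data ships with the package; the phantom generates
atrium-like two-class cines with known truth:

```r
library(lacine)

ph   <- phantom_generate(phantom_spec())      # 30 frames/view, 2 x 2 mm
seg2 <- segment_cine(ph$views[["2ch"]]$cine, ph$views[["2ch"]]$annotation)
seg4 <- segment_cine(ph$views[["4ch"]]$cine, ph$views[["4ch"]]$annotation)
seg2
#> la_segmentation: 30 frames of 128 x 128, mask area 284-465 px

ev <- evaluate_segmentation(seg2, ph$views[["2ch"]]$truth, c(2, 2))
attr(ev, "summary")
#>   metric      mean          sd
#> 1   dice 0.9918902 0.009112167
#> 2 mcd_mm 0.1320288 0.137653431
#> 3  hd_mm 2.0666667 0.365148372

clinical_metrics(seg2, seg4, c(2, 2), c(2, 2))
#> LA clinical metrics: EDV 24.8 ml, ESV 52.5 ml, EF 52.9%, GLS 30.3%
```

The phantom's analytic truth for this study is EF 54.4% and GLS 30.0%,
so the pipeline recovers ejection fraction within ~1.5 points and strain
within ~0.3 points; the per-frame Dice against truth is 0.99. A
command-line front end (`inst/cli/lacine`) exposes `segment`,
`evaluate`, `clinical`, `phantom` and `robustness` subcommands over the
same functions.

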
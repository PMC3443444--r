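---
title: "Measuring DSAEK graft area in anterior-segment OCT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring DSAEK graft area in anterior-segment OCT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octgraft)
```

## The measurement

A DSAEK graft appears in an anterior-segment B-scan as a band attached to
the posterior surface of the recipient cornea. Its cross-sectional area
in µm² integrates graft thickness over the lateral extent and is a more
robust surrogate for graft health than any single-point caliper reading.
`octgraft` produces that area in two modes: a fully automated
segmentation, and a semi-automated mode in which an observer adjusts the
automated curve's control points before the area is computed. Images are
intensity grids normalised to [0, 1]; rows index axial depth (anterior
structures at small row indices), columns index lateral position, and
curves are stored as (col, row) pairs so lateral position is the
independent variable. Coordinates are 1-based, following R's indexing.

## Automated pipeline

**1. Boundary extraction.** The image is optionally Gaussian-filtered
(`preprocess$scale`, default 0 px — the edge detector smooths
internally), then binarised with a Canny detector: Gaussian smoothing at
`canny$sigma` (default 2 px), Sobel gradients, non-maximum suppression to
one-pixel ridges, hysteresis linking over 8-connected components.
Hysteresis thresholds are *quantiles of the gradient magnitude over all
pixels* (`canny$low_q` = 0.80, `canny$high_q` = 0.95) rather than
absolute values, which makes the edge map invariant to affine intensity
rescaling — scans differ in exposure and polarisation tuning, and
quantile thresholds survive that. The boundary is then sampled every
`sampling$step` = 10 columns; coarse sampling suppresses the effect of
speckle on the extracted boundary. Within a sampled column the default
pipeline keeps the *deepest* edge pixel, which traces the posterior-most
boundary: recipient posterior cornea outside the graft span, graft
posterior (endothelial) boundary inside it. Selected rows are refined to
sub-pixel precision by a parabolic fit of the gradient magnitude across
the three rows around the ridge. Columns without an edge pixel are
explicit gaps (NA), never interpolated at this stage.

**2. Corner detection.** The four corner points — where the graft band's
anterior and posterior boundaries terminate at its lateral ends — are
curvature events on the posterior trace. Two complementary local tests
run along the polyline: a k-cosine measure (support half-window
`corner$k` = 5 samples) scored as a robust z-score (median/MAD, MAD
floored at 0.02 so constant-curvature contours never produce spurious
significance) with a minimum turn angle `corner$min_angle` = 25°; and the
discrete second difference of the rows in pixels, thresholded at
max(3 × MAD, 2 px). The second test matters because a shallow graft end
deflects the polyline by only a few pixels — far below any angular
threshold at this support — yet is still a sharp curvature event relative
to the smooth cornea. Candidates cluster at the two graft ends; within
the strongest left and right clusters the anterior (upper) and posterior
(lower) peaks become the labelled corners, with ties broken toward the
larger second difference because the k-cosine measure plateaus within a
half-window of a sharp step. When the edge map is available each corner
pair is refined: the boundary is re-traced at step 1 within ±2 sampling
steps, the largest row jump fixes the corner column, and the corner rows
come from linear extrapolation of the trace from ≥ 3 px outside the
corner zone — edge localisation right at a corner is perturbed by the
two-dimensional blur of the vertical graft end, so rows read off the
jump itself are biased by 1–2 px. Fewer than two candidate clusters is a
corner-detection failure naming the number of candidates found.

**3. Host–graft interface.** The graft's anterior boundary has little
contrast: donor and recipient stroma are the same tissue. For each
sampled column between the anterior corners we search a band above the
posterior boundary for the strongest anterior-directed intensity drop
(most negative axial derivative of the smoothed image, sub-pixel refined)
that is a *local* maximum of the drop — the monotone blur tail of the
posterior edge itself never qualifies. The expected interface position
is anatomical: the interface is the continuation of the recipient
posterior corneal surface, so a circle is fitted (algebraic Kasa fit) to
the boundary trace *outside* the graft span and interpolated across it;
the search band reaches 1.5× the local thickness estimate above the
posterior boundary, never less than `interface$min_depth` = 8 px
(≈ 150 µm at the 18 µm/px default — about one typical graft thickness,
the minimum band that keeps a real graft in view when the corner-based
estimate degenerates). Picks inconsistent with a smooth corner-to-corner
path (residual > `interface$smooth_tol` = 4 px against a
corner-weighted smoothing spline) become gaps; more than
`interface$max_gap_frac` = 50 % gaps raises a low-contrast failure.

This stage is deliberately greedy: wherever *any* consistent drop exists
the automated mode takes it. In thin, low-contrast grafts the true
interface produces no usable drop, the band floor exceeds the graft
thickness, and the strongest drops are speckle events or the recipient
boundary higher up — so the automated area is systematically too large.
That behaviour is intentional and mirrors how such automated readings
fail in practice; a veto-style noise floor would instead refuse exactly
the images whose automated overestimation the package is designed to
expose. The semi-automated mode exists to correct it.

**4. Curve fitting.** Each boundary point set is fitted with a cubic
smoothing spline (smoothing chosen by generalised cross-validation, or
fixed via `spline$spar`), excluding samples within 5 px of a corner
(corner-perturbed edge positions; the corners themselves anchor the fit
there). The curve is then constrained to pass exactly through its two
corners by a cosine-tapered correction confined to ~15 % of the span at
each end: a tapered constraint keeps a sub-pixel corner error local,
where a global linear correction would bias the whole curve and hence
the area. Control points are the sampled columns plus the corners;
evaluation is a natural cubic interpolant through them. A lateral span
below 10 px is a geometry error; curves that cross (negative thickness)
are rejected.

## Semi-automated mode

`adjustControlPoints()` applies explicit edits — curve, index, new
(col, row) — re-interpolates, and re-checks every invariant
(column monotonicity, non-negative thickness, in-image bounds when an
image size is supplied); endpoint edits move the corresponding corner.
On phantoms, `snapSegmentationToTruth()` emulates an idealised observer
who drags all control points onto the visible true boundary; it recovers
the true area to well within 1 %, which is the package's evidence that
the refinement interface is sufficient to correct any automated error.

## Metrics

Area is the absolute shoelace value of the closed polygon (anterior
left→right, posterior right→left, sampled at ≥ 1 point/px) in px²,
scaled by lateral × axial µm/px. The thickness profile is
(posterior − anterior row) × axial calibration at evenly spaced lateral
positions; its trapezoidal integral reproduces the area to within 1 %
(the two discretise the same region differently). The volume estimate
follows the published mixed-unit convention — area in µm² times trephine
diameter in mm, e.g. 20 000 µm² × 8.5 mm = 170 000 — exactly as printed;
a dimensionally consistent µm³ variant (diameter converted to µm) is
available behind `consistentUnits = TRUE`. Fidelity to the printed
arithmetic was chosen as the default because users will compare against
published figures.

## Agreement statistics

For paired series (n ≥ 3, no missing pairs): differences are
first-listed arm minus second. Bias is their mean, spread the sample SD
(n − 1), and the limits of agreement bias ± 1.96 × SD — the 1.96
multiplier is the fixed convention, not a t quantile, while confidence
intervals do use t(n−1): half-widths t·SD/√n for the bias and
t·SD·√(3/n) for each limit. The ICC is the single-measures coefficient
from the two-way model; *absolute agreement* is the default flavour
(the reproducibility default of the clinical packages this mirrors, and
the stricter choice: a constant offset between observers lowers it),
with `type = "consistency"` available. Its 95 % CI uses the
F-distribution bounds with Satterthwaite degrees of freedom. Pearson r
and the paired t-test use their standard definitions; identical arms are
reported as bias 0, LoA (0, 0), ICC 1, r 1, t 0 with an undefined (NA,
flagged) p value, and zero total variance is a degenerate-data error.

## The phantom and what it does not show

`phantomSpec()` renders a 512 × 384 px scan at 18 × 18 µm/px: a bright
corneal band (intensity 0.8, thickness 30 px) under a circular anterior
arc (sagitta 80 px over the full width, matching a ~7.8 mm corneal
radius at this scale), a dark background (0.05), and a lens-shaped graft
between two circular arcs sharing corner endpoints on the posterior
corneal surface — 300 px span, 24 px central and 10 px edge thickness by
default, i.e. a graft on the thick side of the DSAEK range, with
closed-form area. The interface intensity step is
`interfaceContrast` × band intensity (default 0.5); speckle is
multiplicative log-normal with unit mean (σ = 0.1 default, 0.15 in the
stress suites), seeded and bit-reproducible. `randomPhantomSpec()` draws
geometry (span 40–70 % of width, central thickness 16–34 px, edge 6–14
px) so that accuracy claims do not hinge on one fixed shape, and
`thinGraftSpec()` shrinks span and thickness together until the true
area falls below 80 000 µm² — the thin-graft regime — while keeping the
end step resolvable.

The phantom emulates band geometry, interface contrast and first-order
speckle. It does **not** emulate attenuation with depth, refraction,
motion artifacts, saturation streaks, irregular graft cuts, or real
anatomical variability; passing its suites shows the algorithm chain is
correct and noise-tolerant under the stated model, not that it meets any
clinical accuracy bar on patient scans. The published reproducibility
figures (ICC ≈ 0.91–0.97 across 50 patient scans) cannot be recomputed
here because the underlying images and per-image readings were never
deposited; the package instead verifies the arithmetic of the published
agreement tables, the printed worked example, and parameter recovery on
synthetic data.

## Numerical choices and problem sizes

Ties in boundary selection break toward the smaller row; polygon
orientation is normalised by taking |shoelace|; thickness is clamped at
−10⁻⁶ px numerical tolerance; arc sagittas are limited to half the chord
(the minor-segment regime). JSON serialisation keeps full double
precision (≥ 6 decimal digits guaranteed). The test and acceptance
suites use 20 randomised phantoms per accuracy claim (clean: every area
within 2 % of truth; speckle σ = 0.15: within 5 %), 20 thin-graft
phantoms for the overestimation direction (≥ 80 % of automated readings
above the truth-snapped semi-automated ones; failed automated runs count
against the rate), 50 phantoms for the shoelace-vs-rasterisation
cross-check at 0.5 % (the rasterisation oracle counts quarter-pixel
cells so its own quantisation noise stays an order of magnitude below
the band), and n = 200 pairs for observer-noise recovery (bias within
3σ/√n, SD of differences within 10 % of σ√2). These sizes give stable
pass/fail behaviour across seeds at a few seconds per suite.

## Known limitations

Only single-valued (in column) boundaries are representable, so
completely detached or folded grafts are out of scope. The automated
mode assumes both graft ends are visible in the scan, as end corners are
its anchors. Batch semi-automated readings require phantom truth files;
on real images refinement is necessarily interactive via the edit API.
DICOM input, proprietary scanner databases and 3-D volume stacks are not
supported: calibrated PNG/TIFF in, JSON/CSV out.
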
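---
title: "Measuring strawberry shape uniformity from 3D point clouds"
author: "berry3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring strawberry shape uniformity from 3D point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(berry3d)
```

## The measurement problem

Shape uniformity — how close a strawberry is to a solid of revolution about
its central axis — is a key fruit-quality trait in breeding, but manual
1–9 scoring is subjective and cannot resolve some of its geometric
components at all. `berry3d` quantifies uniformity from a coloured 3D
point cloud of a berry sitting on a blue foam reference holder, as
produced by multi-view (structure-from-motion) photogrammetry. The
package takes the reconstruction as given: camera control, image
pre-processing and the reconstruction itself are upstream of this tool.

Two things make raw reconstructions unusable directly: they contain
stray points (background, turntable, speckle), and their coordinate
scale is arbitrary. The pre-processing chain handles both, and the
metric layer then condenses the standardised berry body into eight
numbers.

## Pre-processing model

The chain implemented by `preprocessCloud()` is, in order:

1. **HSV conversion** (`rgbToHSV()`). All colour reasoning is on the hue
   channel, in full degrees in $[0, 360)$. (Tools built on OpenCV store
   hue in $[0, 180]$; configuration values here are always full degrees,
   which removes a silent factor-of-two trap.)
2. **Hue denoising** (`denoiseByHue()`). Points whose hue falls outside
   the configured berry + holder bands are discarded. The thresholds are
   deliberately configuration values, not constants: real rigs differ,
   and the defaults (`c(330, 30)` red, `c(200, 260)` blue) describe the
   synthetic palette of the built-in generator. Intervals may wrap
   through 0°. The calyx, if present in the input, carries green hues
   and is treated as noise under the defaults; the equatorial-band crop
   later provides a second line of defence.
3. **Translation to the origin** (`centerToOrigin()`). The cloud moment
   is the unweighted mean of point coordinates — the simplest estimator
   and exactly idempotent.
4. **Principal-axis alignment** (`alignPrincipalAxis()`). The main
   orientation is the eigenvector of the largest eigenvalue of the point
   covariance (population, $1/N$, normalisation — irrelevant to the
   eigenvectors but fixed for reproducibility). The rotation maps it to
   $+z$. The eigenproblem leaves two free choices that the data must
   disambiguate: the axial **sign** is fixed by sending holder-coloured
   points to negative $z$ (holder down, berry nose up, so height
   fractions are well defined), and the azimuthal frame is whatever the
   minor eigenvectors give — every downstream metric is either
   azimuth-invariant or samples the full turn, so this is immaterial.
   When the top two eigenvalues differ by less than a factor
   $1 + 10^{-6}$ the orientation is undefined; the cloud is passed
   through unrotated and flagged (`flag_degenerate_axis` in the output)
   rather than silently rotated by noise.
5. **Body/holder segmentation** (`segmentBodyHolder()`): a second hue
   threshold, holder band versus everything else. Both segments must
   clear `minSegmentPoints` (default 500) or the cloud is rejected.
6. **Scale standardisation** (`standardizeScale()`). The holder is a
   38 × 19 × 19 mm foam block standing on end; its z-extent in
   reconstruction units fixes the units→mm factor. `holderHeightMm` is
   exposed in the configuration (default 38) in case a rig uses the
   block lying down. After removing the holder the body centroid has
   drifted off the origin; the drift is recorded (`centroidDriftMm`)
   and the body re-centred, which is safe because every metric below is
   translation invariant.

The whole chain is equivariant: pre-rotating or pre-scaling the input
arbitrarily changes the standardised body only at floating-point level,
because the covariance eigenvectors co-rotate exactly with the data and
the holder height cancels the scale. The test suite checks all eight
metrics under 20 random rigid rotations and rescalings per fixture.

## The eight uniformity metrics

All coefficients of variation in this package use the population
standard deviation ($1/N$), consistently.

**Side-view area metrics (CV_A, Max_A/Min_A).** The equatorial band —
the middle 50% of body height, which excludes calyx remnants and the
nose — is rotated about $z$ in $360/n$ steps (default $n = 100$, 3.6°)
and projected onto the $x$–$z$ plane. Each projection is summarised by
the area of its 2D convex hull. A geometric hull rather than a
rasterised silhouette keeps the measure resolution-independent; the
consequence, shared with any convex silhouette, is that concavities are
bridged. CV_A is the population CV of the 100 areas and Max_A/Min_A
their range ratio; an ideal solid of revolution gives 0 and 1.

**Orientation dispersion (CV_D).** Each projection also yields a major
axis (first principal direction of the projected points), an *axial*
quantity defined only modulo 180°. A plain CV of raw angles is ill-posed
— the mean can sit at the wrap-around, or near zero. The convention
here: take each view's axis angle mod 180°, compute the axial circular
mean (by doubling angles), express every view as its signed deviation
from that mean axis in $(-90°, 90°]$, add 90, and take the population
CV. A solid of revolution scores 0; the +90 offset keeps the
denominator near 90 so the statistic is stable for any fruit pose. The
worked example: axes at 80° and 100° about a 90° mean give
$\mathrm{CV_D} = 10/90 \approx 0.111$.

**Slice metrics (L/W, CIR, STR).** One hundred horizontal slice planes
are placed at the centres of 100 equal height cells; each collects the
points within `sliceHalfwidthMm` of it (default: height$/200$, so the
slabs tile the height exactly — a true plane would intersect no sample
points). Each slice's planar point set is summarised by its convex
hull: area, perimeter, and the *polygon* centroid. The polygon centroid
is the geometric analogue of an image-moment contour centroid and,
unlike the mean of member points, does not depend on sampling density.
Slices with fewer than three non-collinear points (e.g. at a cone apex)
are marked invalid and skipped.

* **L/W** is the aspect ratio of the bounding box of the largest slice,
  aligned with the slice's principal directions; ties in the
  largest-slice search go to the lower index (the holder side) so
  outputs are deterministic.
* **CIR** is the isoperimetric quotient $4\pi A / p^2$ of the largest
  slice's hull: 1 for a circle, smaller otherwise; the isoperimetric
  inequality caps it at 1 up to float error, which the record validates.
* **STR** connects the centroids of the slices in the middle 80% of body
  height (80 of the 100 slices) into a polyline and divides its length
  by the distance between the first and last centroid. Distances are 3D:
  the even z-spacing dominates each segment, so STR has a hard floor of
  1 and grows as the centre axis bends. Invalid slices inside the window
  are bridged, not fatal.

**Curvature metrics (CV_C, Max_C/Min_C).** Curvature estimation is
noise-sensitive, so the body is first smoothed by moving least squares
(`mlsSmooth()`): each point is projected onto a degree-2 polynomial
fitted by Gaussian-weighted least squares over its radius neighbourhood
in the local tangent frame. The default radius is
`mlsRadiusFactor = 2.5` times the *effective point spacing*. The
effective spacing is defined as twice the mean nearest-neighbour
distance: for Poisson-like surface samples of density $\lambda$ the
mean nearest-neighbour distance is $0.5/\sqrt{\lambda}$, so the
definition recovers the lattice-equivalent spacing $1/\sqrt{\lambda}$
and the default radius supports roughly 20 points — enough for the
six-coefficient fit. Points with fewer than six neighbours are copied
through unsmoothed and counted (`unsmoothed_frac`).

Per-point principal curvatures come from a quadric height field
$z' = a x'^2 + b x' y' + c y'^2$ fitted over the `kNeighbours = 30`
nearest neighbours in the local tangent frame; $k_1 \ge k_2$ are the
eigenvalues of $\begin{pmatrix} 2a & b \\ b & 2c \end{pmatrix}$, signed
so that locally convex surface is positive (sphere of radius $R$:
$k_1 = k_2 = 1/R$; cylinder of radius $r$: $k_1 = 1/r$, $k_2 = 0$ —
these closed forms are the module's primary oracle, checked at 5–10%).
The average curvature is $(|k_1| + |k_2|)/2$. This estimator scales
exactly as $1/c$ under uniform scaling, so the two summary metrics are
scale-free.

Sixteen patches are seeded at 22.5° intervals around the largest-slice
centroid; each seed is the slice point nearest its direction and its
patch is the `patchK = 200` nearest body points. The patch curvature is
the mean of the upper half of its members' average curvatures (median
element included on the upper side for odd counts), which emphasises
creases and bumps over flat regions. CV_C and Max_C/Min_C are the
population CV and range ratio of the 16 patch values. If a patch
curvature is non-positive (flat or saddle patch) the ratio is undefined
and flagged (`flag_missing_max_min_c`) rather than reported.

## The synthetic-berry generator

`generateBerry()` exists so that the entire pipeline is testable with
exact ground truth and no imaging hardware. A berry is a surface of
revolution $r(z)$ — cylinder, cone, sphere, or a smooth "berry" spline
with a rounded base, widest point at 40% height and a tapering nose —
optionally deformed by angular lobes
$r(z,\theta) = r(z)\,(1 + a\cos m\theta)$ and a lateral axis offset
(sine or circular arc; an arc of amplitude $H/2$ is an exact semicircle,
whose arc/chord ratio $\pi/2$ anchors the straightness oracle). Surface
points are *area-weighted* samples (cell-multinomial over a fine
$(z,\theta)$ grid with the numerical area element), so slice point
counts reflect local circumference — uniform-in-$z$ sampling would
starve the nose and flatter the hull estimates. The holder is sampled on
the faces of a 38 × 19 × 19 mm block below the base; stray noise points
(uniform in a padded box) take hues in $[65°, 175°]$, disjoint from the
berry and holder bands, so hue segmentation has an exact ground truth.
A rigid tilt and an arbitrary global scale are applied last and
recorded. One RNG stream per call, seeded from the spec, makes every
cloud bit-reproducible.

Default scene size is 50,000 points, a plausible density for a
single-fruit photogrammetric reconstruction; at that size a noise-free
solid of revolution scores CV_A, CV_D < 0.005 and Max_A/Min_A,
L/W < 1.005 — zero and one to two decimals.

What the generator does *not* emulate: achenes and surface texture,
partial occlusion of the nose (real reconstructions under-sample it),
reconstruction artefacts correlated along viewing rays, and natural
calyx remnants. Passing the synthetic suite therefore demonstrates the
geometry and statistics are computed correctly, not that hue thresholds
or smoothing radii are optimal for any particular rig.

## Numerical choices and degenerate inputs

* Convex hulls come from `grDevices::chull`; area (shoelace), perimeter
  and polygon centroid are computed from the hull cycle. Tests compare
  them against a brute-force extreme-edge oracle, exactly.
* Collinear or sub-3-point slices are invalid; an all-invalid stack, an
  empty equatorial band, a holder with no z-extent, or a segment below
  `minSegmentPoints` are hard errors. In batch mode `runSingle()`
  converts any stage failure into an error row
  (`IO_PARSE`/`PREPROCESS`/`METRICS`) so one bad reconstruction cannot
  kill a breeding-scale run.
* The measurement path consumes no random numbers: identical input and
  configuration give identical rows, and batch output is independent of
  file order (files are processed sorted).
* Rank-deficient curvature fits are flagged per point and excluded from
  patches; an entirely flagged patch is a hard error.
* The effective configuration is hashed (MD5 of its canonical JSON) into
  every output row, so a metrics table is traceable to its tunables.

Problem sizes in the shipped tests were chosen to keep the full suite
in the low minutes on one core: unit fixtures use 4,000–30,000-point
scenes, the ideal-solid and curvature oracles run at the 50,000-point
default, and the invariance suite re-measures six fixtures under 20
random transforms each at 20,000 points.

## Known limitations

* Convex silhouettes and slices bridge concavities by construction;
  deeply creased fruit read as more uniform than they are.
* CV_D compares axial angles of projections; for fruit whose equatorial
  band is wider than it is tall the major axis is nearly horizontal in
  every view and small sampling noise moves the angles more than for
  elongated fruit — CV_D is the noisiest of the eight metrics on
  near-ideal solids.
* Curvature patches approximate vertical stripes around the equator via
  k-nearest-neighbour balls about contour seeds; patch extent therefore
  scales with point density, not with a fixed physical window.
* PLY input is vertex-only (ASCII or binary little-endian); faces are
  ignored and other mesh formats are out of scope.
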
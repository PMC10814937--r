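---
title: "Colorimetric analysis of skin-lesion photographs: models and methods"
author: "LesionColor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colorimetric analysis of skin-lesion photographs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LesionColor)
```

## The problem

Merkel cell carcinoma (MCC) is a rare, highly aggressive neuroendocrine
skin cancer whose red-to-purple nodules are easy to mistake for benign
vascular lesions (cherry angiomas, hemangiomas) or for the common
non-melanoma carcinomas (BCC/SCC). LesionColor quantifies the color of a
lesion and of the skin immediately around it from an ordinary clinical
photograph, and asks whether those numbers separate MCC from its
look-alikes.

The pipeline is: delineate the lesion border; build an annular
normal-skin reference band around it; average color inside each region
in RGB and CIELab; summarize the lesion-induced color shift with the
Individual Typology Angle (ITA); compare diagnosis groups with exact
Mann-Whitney U tests; and evaluate single-parameter threshold rules with
a full confusion matrix.

## Color model

Images are assumed to be 8-bit sRGB. The conversion to CIELab follows
the standard chain: the IEC 61966-2-1 transfer function linearizes each
channel, a fixed 3x3 matrix maps linear RGB to CIE XYZ under the D65
white point (2-degree observer), and the usual cube-root compression
yields $(L^*, a^*, b^*)$. No ICC profiles, RAW decoding or white-balance
correction are attempted: clinical photographs in this setting carry no
color management, and the analysis compares a lesion against its *own*
surrounding skin under the same illumination, which cancels much of the
camera dependence.

A note on axis conventions: we follow the CIE convention throughout —
positive $a^*$ is red, negative green; positive $b^*$ is **yellow**,
negative blue. Some clinical texts describe positive $b^*$ as "blueness";
that reading inverts the CIE axis and is treated here as an erratum.

The Individual Typology Angle is

$$\mathrm{ITA} = \arctan\!\left(\frac{L^* - 50}{b^*}\right)\cdot\frac{180}{\pi},$$

in degrees. It was designed as a spectrophotometric skin-phototype
index (higher = lighter skin); here it serves as a compact indicator of
the color change a lesion induces. The formula is undefined at
$b^* = 0$; the package uses the limiting convention $+90$ for
$L^* > 50$, $-90$ for $L^* < 50$, and $0$ at $L^* = 50$. All 46 records
of the packaged cohort satisfy the identity between their printed
$L^*$, $b^*$ and ITA to within 0.04 degrees, which is also the
consistency the synthetic cohort generator enforces.

```{r ita}
itaFromLab(65.79, 25.28)
```

### Averaging choices

Two deliberately exposed choices:

* **Lab means** are computed per pixel and averaged
  (`labMode = "perpixel"`), not by converting the mean RGB
  (`labMode = "meanrgb"`). Lab is nonlinear in RGB, so the two differ on
  heterogeneous regions; per-pixel averaging is the perceptually
  standard choice, and the alternative remains a switch.
* **Region ITA** is the ITA of the mean $(L^*, b^*)$
  (`itaMode = "meanlab"`), not the mean of per-pixel ITAs. The packaged
  cohort's ITA column is row-by-row consistent with the formula applied
  to the printed mean $L^*$ and $b^*$, which motivates this default;
  per-pixel averaging is available (`itaMode = "perpixel"`). For full
  images neither choice is provably what any given acquisition software
  used — the fixture consistency only constrains the tabulated data.

## Border, band and geometry

**Manual mode.** `closeBoundary()` closes operator-placed border points
with a periodic uniform quadratic B-spline. With one control point per
input point, the least-squares collocation system is square and
nonsingular, so the minimizing spline interpolates the clicks (zero
residual — never worse than the straight polyline) while staying smooth
between them. Twelve points on a circle of radius 50 px are reproduced
to within 0.05 px. A caveat: with strongly oscillating inputs (large
radial jumps between adjacent clicks) the interpolant can loop and
self-intersect; the `ClosedBoundary` validity check rejects such curves
explicitly rather than passing them downstream.

**Automatic mode.** `autoSegment()` implements one defensible automatic
border finder for a single dominant lesion: Euclidean Lab distance from
the median color of the image-border pixels (assumed skin), Otsu's
threshold on that distance map, morphological closing (disc, default
radius 5 px), largest connected component, contour trace. Components
below 100 px raise a classed failure condition that invites manual
delineation. On the default synthetic scene (below) it recovers the
true mask with Dice 1.00 at noise sd 5.

**Normal-skin band.** The reference band is a geometric enlargement:
the border polygon is scaled by a factor of 1.25 about its area
centroid, and the band is the set of pixels inside the scaled border
but outside the original. Scaling — rather than morphological dilation
by a fixed pixel count — keeps the band's width proportional to lesion
size and is parameter-free beyond the single factor; the factor must
exceed 1 and defaults to the +25% used throughout. Rasterization uses
pixel-center containment with the even-odd rule (0-based coordinates,
y down). For a circle of radius 40 px the band area matches the annulus
formula $\pi r^2(1.25^2 - 1)$ to within 1%, and band/lesion masks are
disjoint by construction.

**Geometry.** With a ruler calibration (`calibrateScale()`:
cm-per-pixel from two marked points a known distance apart),
`geometryFeatures()` reports maximal diameter (exhaustive pairwise
vertex distance), surface (shoelace area) and perimeter (edge sum).
Validity enforces $d \le P/2$ and the isoperimetric inequality
$4\pi A \le P^2$.

## Cohort statistics

Group comparisons use the Mann-Whitney U test with the reporting
conventions of mainstream statistical software, because the packaged
cohort's published statistics follow them and internal consistency is
only obtained under this reading:

* midranks for ties;
* $U = \min(U_1, U_2)$ and $W$ = the **smaller** of the two rank sums
  (e.g. a red-channel cell with $W = U + 12\cdot13/2$ next to a green
  cell with $W = U + 11\cdot12/2$ is only coherent if $W$ tracks
  whichever group has the smaller rank sum);
* tie-corrected normal approximation
  $Z = (U - n_1 n_2/2)/\sigma_{\text{tie}}$, **without** continuity
  correction (the printed $|Z| = 3.016 \Rightarrow p = 0.003$ cells
  reproduce only without it), so the reported $Z$ is always $\le 0$;
* asymptotic significance $2(1 - \Phi(|Z|))$;
* exact significance $2 \times P(U' \le U)$ from the tie-free null
  distribution of $U$, capped at 1 (the small-sample "2 x one-tailed"
  report). The null distribution is computed by dynamic programming
  over rank subsets (`mwExactDistribution()`), verified in the tests
  against brute-force enumeration for all $n_1 + n_2 \le 10$ and
  against `wilcox.test()`'s exact p on tie-free draws.

When every pooled value is identical, $\sigma_{\text{tie}} = 0$: $Z$
and the asymptotic p are reported `NA` with a classed warning, and the
exact p is 1.

```{r mw}
fx <- loadStudyFixture()
comparisonTable(fx, "MCC", "HEMANGIOMA")
```

The packaged cohort reproduces its published MCC-vs-BCC/SCC and
MCC-vs-hemangioma tables cell for cell. The published MCC-vs-cherry
table does **not** follow from the published per-patient values
(recomputation gives U of 18 and 4 for blue and $b^*$ where 17.5 and 5
were printed, among others); the package reports the recomputed values
and the discrepancy is covered by a regression test rather than
reverse-engineered.

No multiple-testing correction is applied, matching the original
analysis; the 21 per-patient variables and 7-parameter tables are
descriptive, not confirmatory.

### Why the type-I simulation uses two groups of 8

The exact U test is discrete: at small samples its attainable two-sided
level can sit well below a nominal 0.05. At the study's own sizes
(11 vs 12) the largest attainable level under 0.05 is 0.0439 — a
simulation there would measure discreteness, not correctness. At
$n_1 = n_2 = 8$ the attainable level is 0.0499, so the nominal 5% is
essentially achievable and a calibration check is meaningful. The test
suite therefore draws 2000 seeded pairs of identical $N(0,1)$ groups of
8 and checks the rejection rate of `pExact < 0.05` against the binomial
95% interval around 0.05.

## Threshold diagnostics

`applyRule()` evaluates a single-parameter threshold rule between a
positive and a negative class and reports raw counts with the five
derived percentages (sensitivity, specificity, accuracy, PPV, NPV) at
full precision; a zero-denominator metric is `NA` and flagged, never
silently 0. A value exactly at the threshold is called positive (no
record of the packaged cohort sits exactly at the documented a* = 37
threshold, so its published metrics are insensitive to this
convention). Display helpers render both two-decimal and one-decimal
truncated forms, since clinical reports sometimes truncate (8/12 shown
as 66.6%).

```{r rule}
applyRule(fx, thresholdRule("a", 37), "HEMANGIOMA")
```

`separationScan()` scans every midpoint between adjacent sorted values
(both directions) for the threshold maximizing sensitivity +
specificity, with deterministic tie-breaks, and flags perfect
separation. On the packaged cohort, neither $b^*$ (MCC vs cherry) nor
$a^*$ (MCC vs BCC/SCC) admits a perfect threshold — the printed value
ranges overlap — although summary claims of 100%/100% circulate for
both; the tests pin the true exhaustive optima instead. No ROC/AUC
machinery or cross-validation is provided: with 46 records evaluated
in-sample, a fuller apparatus would suggest more rigor than the data
support.

## Synthetic data

`generateLesionImage()` emulates the features of the study photographs
that matter to the pipeline: a noisy skin-colored field (default RGB
(220, 180, 160), per-channel Gaussian sd 5 — typical of consumer-camera
skin patches), one rotated elliptical lesion of a redder, darker mean
color (default RGB (180, 70, 90), sd 5, semi-axes 70 x 50 px in a
256 x 256 frame), an optional central specular highlight emulating a
flash reflection on a vaulted lesion, and optional ruler tick marks a
known distance apart. Pixels are quantized to 8 bits and clipped to
[0, 255]; generation is byte-deterministic given the seed. Ground truth
(exact ellipse boundary, rasterized masks, scale) is returned alongside.

What it does **not** emulate: skin texture, hair, vignetting,
illumination gradients, JPEG artifacts, or multi-lesion scenes. Passing
recovery tests on these images therefore demonstrates correctness of
the measurement chain, not robustness to real-world photography.

`generateCohort()` draws per-diagnosis feature vectors from a
multivariate normal (default: the packaged cohort's group means and
diagonal per-group variances at the study's group sizes 11/11/12/12),
then recomputes ITA from the sampled $L^*, b^*$ so every record
satisfies the ITA identity. Gaussian noise is chosen for analyzability
(CLT bounds in the recovery tests are exact); heavier-tailed
alternatives can be emulated by supplying a custom covariance or
post-processing, and the cohort validity checks still apply.

The packaged 46-record cohort itself ships as a checksum-pinned CSV;
`loadStudyFixture()` refuses a modified file. Group sizes follow the
body of the table and the arithmetic of the published predictive values
(9/13 and 8/10 require 12 hemangiomas), not a caption that says 11.

## Numerical choices and degenerate inputs

* All internal computation is double precision; rounding to 2 decimals
  (features, group means) or 3 (test statistics) happens only at
  serialization.
* One published group-mean cell is an exact half-ulp rounding tie
  (a mean of exactly 108.735 printed as 108.73); the reproduction test
  accepts either direction of the tie, i.e. agreement within half a
  unit in the last printed place.
* Polygon simplicity is verified by exhaustive proper-crossing tests up
  to 800 vertices; denser contours come from the tracer, which emits
  simple chains by construction.
* Degenerate inputs fail loudly with classed conditions: empty masks,
  empty classes, < 4 or collinear spline points, coincident ruler
  points, uniform images (segmentation), all-tied samples (Z), non-PSD
  covariances, bands with factor <= 1, tampered fixture files.

## Problem sizes

The shipped tests run the full pipeline at the sizes used throughout
this vignette: 256 x 256 synthetic scenes (~11,000 lesion pixels), the
46-record cohort, exact-test enumeration up to $n_1 + n_2 = 10$, and
2000 replicates for the calibration simulation — the whole suite
completes in well under a minute on one core.

## Known limitations

* The published single-case geometry (3.04 cm diameter, 6.73 cm²,
  9.40 cm) cannot be checked without the original photograph; geometry
  is validated against closed forms (squares, circles, random convex
  polygons) instead.
* The two published 100%/100% separation claims and the MCC-vs-cherry
  statistics table are inconsistent with the published per-patient
  values; the package documents and tests the recomputed quantities.
* Automatic segmentation assumes one dominant lesion against
  surrounding skin reachable from the image border; it is not a general
  dermoscopy segmenter and no learning-based method is included.
* Colors are analyzed as recorded by the camera; cross-photograph
  comparability relies on the within-image lesion-minus-normal design,
  not on calibration.
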
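---
title: "Measuring muscle cross-sectional area in panoramic ultrasound: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring muscle cross-sectional area in panoramic ultrasound: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AcsaScan)
```

## The measurement problem

The anatomical cross-sectional area (ACSA) of the rectus femoris (RF) and
vastus lateralis (VL) is a standard morphological outcome in exercise and
rehabilitation science. Because these muscles are wider than a linear
ultrasound transducer, they are imaged with extended-field-of-view (EFOV)
panoramic sweeps, and their ACSA is traditionally measured by manually
digitising the muscle boundary — slow, and dependent on the investigator.

AcsaScan implements a semi-automatic alternative as a scriptable pipeline:

1. **Calibration.** The pixel grid is mapped to centimetres either from
   two user-supplied points spanning the scanning depth (`manualScale()`)
   or by detecting the scale line most EFOV exports embed
   (`detectScaleLine()` / `autoScale()`). Area converts by `pxPerCm^2`.
2. **Pre-processing.** `buildOutlineMask()` smooths the image (Gaussian,
   `gaussianSigma`), enhances sheet-like structure with a Hessian
   tubeness filter (`tubenessSigma`), runs a Canny edge detector on the
   enhanced image, binarises at `contrastThreshold`, and removes
   connected components shorter than `minLengthFac` times the image
   width. The result is a binary mask of candidate aponeurosis pixels.
3. **Boundary tracing.** From interior starting points, scanning beams
   step outward pixel by pixel until they cross the mask
   (`traceOutline()`). The RF uses one point and a radial fan (default
   1° steps); the VL uses three points, vertical beams from positions
   interpolated along the polyline through them, and horizontal/diagonal
   beams from the endpoints.
4. **Polygon and area.** Hits are deduplicated, sorted clockwise about
   their centroid (`sortClockwise()`), optionally edited
   (`editOutline()`), and measured with the shoelace formula
   (`polygonArea()`), giving cm² via the calibration.

All coordinates are (row, col), 1-based, origin at the top-left, rows
increasing downward. "Clockwise" means clockwise on screen under that
convention (ascending `atan2(drow, dcol)` about the centroid, ties broken
by ascending radius).

## Parameters that matter

| Parameter | Unit | Default | Role |
|---|---|---|---|
| `depthCm` | cm | required | physical span of the scale line |
| `gaussianSigma` | px | 2 | speckle damping before ridge enhancement |
| `tubenessSigma` | px | 5 | scale of the ridge filter; pick ≈ half the aponeurosis width |
| `contrastThreshold` | grey value | 50 | binarisation of the enhanced image; beam-break level |
| `minLengthFac` | fraction of width | 0.05 | length cut-off for mask components |
| `angularStepDeg` | degrees | 1 | RF radial beam spacing |
| `stepPx` | px | 5 | VL polyline beam spacing |

The defaults target aponeuroses several pixels thick, as in typical EFOV
exports. The phantoms below draw a 3-px boundary band, so phantom
analyses use `phantomPreprocessParams()` (`tubenessSigma = 2`): standard
scale-space matching, the filter scale should be about half the full
width of the ridge it enhances.

## Numerical design choices

**Tubeness on an absolute scale.** The ridge response is the magnitude of
the most negative eigenvalue of the γ-normalised (×σ²) Gaussian Hessian,
zeroed where the smallest eigenvalue is non-negative. A scale-matched
ridge of contrast C peaks near C/4, so the response is multiplied by 4
and clipped to [0, 255] rather than rescaled by the per-image maximum.
This keeps `contrastThreshold` an absolute grey value and — importantly —
means a structure-free image (pure speckle) produces a dark response
instead of having its noise stretched to full range. The discrete
second-derivative kernel is normalised to zero sum so constant images map
to exactly zero.

**Canny settings.** Gradient at σ = 1 with hysteresis thresholds at the
70th/90th percentiles of the gradient magnitude among genuine edge
candidates (magnitude above 5% of the maximum; including the
numerically-zero background would collapse the percentiles to noise
level). Edges enter the mask only where the tubeness response reaches
half the contrast threshold, so speckle edges cannot chain into spurious
long objects.

**Beam refinement.** The classic beam-break rule ("first pixel above the
threshold") lands on the near edge of the aponeurosis band and biases
the polygon inward by half the band width — on a 480×640 ellipse phantom
that alone is a few percent of area. `castBeam(refine = TRUE)` (the
tracing default) therefore continues while pixels stay supra-threshold
(up to `maxRun = 20` px, guarding against running along a tangential
band) and returns the midpoint of the run, centring each vertex on the
band. `refine = FALSE` reproduces the plain beam-break contract.

**Component length.** For removal of short objects, component length is
the major-axis length of the second-moment ellipse — the right notion
for thin curvilinear structures. For measuring the scale-line length,
the maximum pairwise pixel distance (Feret diameter) is used instead,
because the moment-based major axis of a uniform segment overestimates
its length by a factor 2/√3 and the calibration must be accurate to
better than 2%.

**Scale-line detection.** Otsu threshold; compact particles (area
> 50 px² with eccentricity < 0.97 — blobs and closed aponeurosis bands,
not thin lines) are subtracted; the cleaned image is smoothed and
ridge-enhanced; surviving components are screened for line-like geometry
(eccentricity ≥ 0.98) within the configured length range, by default
0.5–1.0 × image height. The length is measured on the thresholded image
so endpoints stay crisp. A restriction to *all* components above 50 px²
would erase the scale line itself (a 200 × 2 px line is 400 px²), hence
the eccentricity condition.

**Degenerate inputs.** Coincident manual scale points, non-positive
sigmas and depths, collinear point sets, zero-area polygons and
out-of-range edit indices raise validation errors; an absent scale line
raises a `scaleNotFound` condition (fall back to manual scaling) and an
empty trace raises `outlineNotFound`. Self-intersection after clockwise
sorting is a warning, not an error — non-star-shaped boundaries can
produce it legitimately and the edit API is the remedy. ICC and
standardized bias on zero-variance input return NaN with a warning.

## The reliability battery

For paired measurements (two methods, two investigators, or test–retest),
`reliabilityReport()` computes:

- **ICC(3,1)** — two-way mixed, single measures, consistency — with the
  F-based 95% compatibility interval. This form treats the two "raters"
  as fixed, which matches comparing two analysis methods or two specific
  investigators. For longer trial sequences,
  `iccConsecutivePairwise()` applies it to each consecutive pair.
- **SEM (typical error)** = SD of the difference scores / √2, with
  chi-square interval on n − 1 df. For two trials this equals the square
  root of the ANOVA residual mean square; the test suite checks that
  identity against `aov()`.
- **MDC** = SEM × 1.96 × √2 ≈ 2.7719 × SEM.
- **Bland–Altman** bias and ±1.96 SD limits of agreement, plus an OLS
  proportional-bias check (slope of differences on means, two-sided
  t-test at α = 0.05).
- **Standardized mean bias** = bias / pooled between-subject SD of the
  two trials, labelled small / moderate / large / very large / extremely
  large at |bias| thresholds 0.3 / 0.6 / 1.0 / 2.0.

Conventions: differences are `trialA − trialB` throughout, so a positive
bias means trial A reads higher; SEM% is relative to the grand mean of
both trials. The standardizing denominator is the pooled between-subject
SD (the natural choice when neither trial is a gold standard).

## What the phantoms emulate — and what they do not

`generatePhantom()` builds an EFOV-like test image: multiplicative
Rayleigh speckle (the standard first-order model of fully developed
ultrasound speckle; unit mean, variance `speckleVar` before its 1-px
correlation smoothing), a mildly brighter interior region, a bright
boundary band of known width along an ellipse, rectangle or star-shaped
Fourier blob of analytically known area, an optional contiguous boundary
gap of a given arc-length fraction (emulating the low-contrast stretches
where real aponeuroses fade), an embedded vertical scale line of known
physical length, and optional bright blob artefacts. The seed fully
determines the image. `generateQuadricepsPhantom()` places two disjoint
regions for the two-muscle modality.

Phantoms deliberately do **not** model beamforming physics, depth-
dependent attenuation or resolution, anatomically realistic muscle
texture, fascicle echoes inside the muscle, or out-of-plane artefacts of
panoramic stitching. Passing the phantom suite therefore shows the
geometry, calibration and statistics are correct and the pipeline is
robust to first-order speckle — not that segmentation succeeds on any
real scan. On real images the quality of the outline still depends on
aponeurosis contrast, and manual correction (`editOutline()`) remains
part of the intended workflow; the gap-phantom experiments, where the
freerun error consistently exceeds the error after repairing the gap,
reproduce exactly that necessity.

Default study conditions used by the verification suite: 480×640 px
phantoms, 3-px boundary at grey 220 over a 40/60 background, speckle
variance 0.05 for noisy conditions, scale line of 0.75 × image height
spanning a 5-cm depth, and for the statistics simulations 60 subjects,
between-subject SD 4 cm², typical error 0.6 cm², bias 0.2 cm² (grand
mean 25 cm², a typical VL ACSA). The acceptance script runs 50 phantom
measurements, 1000 polygon-oracle comparisons (10⁶-cell rasterisation
each), 500 simulated reliability datasets and 50 gap-repair pairs; these
sizes keep the full run to a few minutes on one core while leaving the
Monte-Carlo error well below the tolerances being checked.

## Interpretations where the original workflow was interactive

The original analysis of this kind runs as an interactive ImageJ macro.
Porting it to a library required fixing several things the interactive
tool leaves to the user or leaves unstated:

- Interactive dialogues (artefact selection, point placement, outline
  adjustment, manual scale line) become per-image JSON sidecars and the
  `editOutline()` API; batch runs are therefore exactly reproducible.
- The VL beam layout (which orientations from which points) is not fully
  specified anywhere; the layout implemented — vertical beams along the
  polyline, a leftward beam from the leftmost point, a rightward/downward
  fan from the rightmost — matches images with the medial border on the
  left and the lateral border at the bottom right, and is configurable.
- Whether beams scan the pre-processed mask or the raw greyscale is
  unstated; beams here scan the mask, which makes the beam threshold and
  the binarisation threshold one and the same parameter.
- The contrast threshold is applied to the tubeness-enhanced image (not
  the raw or merely smoothed one): that is the image in which
  "aponeurosis" is actually the bright class.
- Fixed-pixel starting points ship as documented placeholder defaults;
  they are acquisition-protocol specific by nature.
- The automatic scale-line length range is relative (0.5–1.0 × image
  height) rather than hardcoded in pixels, since depth markers span most
  of the image height in EFOV exports.

## Known limitations

- Single-scale tubeness: aponeuroses much thicker or thinner than
  `2 × tubenessSigma` respond weakly; there is no multi-scale maximum.
- Non-star-shaped muscles can defeat centroid-based clockwise sorting
  (reported as a self-intersection warning); strongly concave boundaries
  need manual edits.
- The radial RF scan assumes the starting point sees the whole boundary;
  a point far off-centre in a crescent-shaped muscle will not.
- Between-day reliability modelling and >2-rater mixed models are out of
  scope for the statistics battery.
- No DICOM input; PNG/TIFF/BMP rasters only.
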
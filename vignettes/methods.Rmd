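---
title: "Measuring right-heart strain indices from CTPA segmentation masks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring right-heart strain indices from CTPA segmentation masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctpaindices)
```

## What is measured, and how

The package turns a labeled CTPA volume — an integer mask per anatomical
structure (left ventricle, right ventricle, pulmonary artery, ascending
aorta, lungs), with voxel spacing in mm — into three axial indices of
right-heart dysfunction.

**Coordinate convention.** Arrays are indexed `[z, y, x]`, 1-based (the
native R convention; slice, row and column indices in all outputs are
therefore 1-based). `x` increases towards the image right of a standard
radiological axial display (patient left), `y` towards the image bottom
(posterior), `z` towards the head. Volumes carrying NIfTI orientation
metadata are reoriented to this convention on read; "horizontal" in every
construction below means parallel to the machine `x` axis. Files without
orientation metadata are assumed to already follow it — patient orientation
cannot be recovered from pixel data alone, and this is the dominant
convention for axial mask exports.

**Slice selection.** RV/LV and the septal angle are measured on the axial
slice maximizing the combined LV + RV voxel count; PA/AA on the slice
maximizing the PA voxel count alone (even if the aorta is sub-maximal
there). Ties resolve to the lowest slice index.

**Diameters.** A structure's diameter is its *maximal same-row horizontal
chord*: for every row intersecting the mask, take the chord from the row's
leftmost to rightmost mask pixel; keep the row with the widest pixel span
(ties → lowest row). Length is pixel-center to pixel-center:
`(x_right − x_left) · dx` mm, so a single-pixel mask has diameter 0. This is
the only reading under which the connecting line is literally parallel to
the x-axis, and it makes every expected value in the tests exact. Before
chord extraction each mask is reduced to its largest 4-connected component
with interior holes filled — raw network masks may contain specks or small
holes, and this makes the measurement deterministic and robust without
changing the result on clean masks. RV/LV is the RV chord divided by the LV
chord. (The index is RV-over-LV; values above 1 indicate RV dilation.)

**Septal angle.** On the heart slice, the septal line is by default the line
through the two ventricular centroids (`mode = "centers"`). An alternative
construction (`mode = "closest_midline"`) finds, for every RV boundary
pixel, its nearest LV boundary pixel, keeps pairs within 1.5× the global
minimum pair distance, and fits a total-least-squares line through the pair
midpoints; both readings of "the line characterizing the septum" are
implemented because both appear in practice, and the centroid line is the
default because it is the one used in the angle definition. The reference
axis is the line through the uppermost and lowermost lung pixels of the
*same* slice (ties → lowest x), passing through their midpoint — a
spine-parallel axis that needs no vertebral segmentation. Both lines are
scaled by `(dy, dx)` into physical mm coordinates before the angle is
taken — angles are only meaningful in physical space when spacing is
anisotropic — and the angle is `arccos(|d₁·d₂|) · 180/π`, insensitive to
direction sign and always in [0°, 90°].

Under these conventions the three indices are invariant to integer
translations of the masks and to uniform in-plane rescaling, and the septal
angle is stable under rigid in-plane rotation of the whole slice (both
lines co-rotate; residual changes are rasterization noise below about one
degree). These properties are asserted in the test suite.

## Agreement statistics

- **Dice** `2|X∩Y|/(|X|+|Y|)` compares two masks; both masks empty is an
  error, not a number.
- **ICC.** The formula `(MS_R − MS_w)/(MS_R + (k−1)·MS_w)` is exactly the
  one-way random-effects, single-rater ICC(1,1), with `MS_R` the
  between-subject and `MS_w` the within-subject mean square over an n × k
  ratings table. The 95% interval uses the exact F method
  (`F = MS_R/MS_w` on `(n−1, n(k−1))` degrees of freedom, bounds mapped
  through `(F/F* − 1)/(F/F* + k − 1)`), the standard choice when only a
  confidence level is specified. A perfectly agreeing table returns ICC 1
  with a degenerate interval; an all-identical table is an error; negative
  ICCs are returned as computed.
- **Accuracy.** "Correct" is defined as relative agreement:
  `|auto − manual|/|manual| ≤ rel_tol`, with `rel_tol = 0.10` by default and
  configurable — a deliberate operationalization, since percent-style
  accuracy for continuous measurements requires a tolerance. Its uncertainty
  is a seeded bootstrap standard error (1000 resamples).
- **Bland–Altman.** Differences `auto − manual`: bias = mean, limits of
  agreement `bias ± 1.96·SD` with the sample (n−1) standard deviation.

The implementation computes mean squares directly from the ratings table;
the test suite checks it to 10⁻¹⁰ against an independent route through
`lm()`/`anova()` and against a frozen hand-worked 3×2 table, plus a
known-variance simulation (equal subject and rater variance, expected
ICC 0.5).

## The phantom generator

Every test surface is synthetic: a parametric axial chest phantom with
closed-form ground truth.

- **Ventricles**: axis-aligned ellipses (semi-axes `a` horizontal, `b`
  vertical, in mm; defaults 22/14 mm RV, 20/16 mm LV). Their centers are
  separated along a direction making `theta_sep_deg` (default 40°) with the
  vertical lung axis, at a distance leaving a `gap` (default 6 mm) between
  the boundaries. Because the ellipses stay axis-aligned, the horizontal
  chord at the peak slice is exactly `2a`, and because centers are snapped
  to pixel centers, rasterized footprints are symmetric and mask centroids
  equal the analytic centers: ground truth never depends on the measurement
  code. A crescent-shaped RV would be more anatomical but has no closed-form
  chord, which is the whole point of the phantom.
- **Vessels**: circles (defaults r\_PA 16 mm, r\_AA 14 mm) with the PA
  radius following a symmetric elliptical z-profile peaking at a known
  slice; the profile's discrete area margin between neighboring slices is
  several percent, so the peak slice is the unique area argmax after
  rasterization.
- **Lungs**: two identical ellipses symmetric about the midline spanning
  most of the craniocaudal extent, so the lung extreme pixels define an
  exactly vertical reference axis.
- **Layout** is parameterized by fractions of the field of view, so the same
  anatomy renders on the default 24 × 256 × 256 grid at (5, 0.7, 0.7) mm —
  clinical-like in-plane resolution — and on 8 × 64 × 64 toy grids at
  2.8 mm for segmentation experiments. Structure placement guarantees
  pairwise disjointness across the default sampling ranges, and generation
  re-checks disjointness after rasterization and aborts on any overlap.

Cohorts draw parameters uniformly from ranges chosen to span clinically
plausible values (RV/LV roughly 0.7–1.5, PA/AA 0.75–1.5, septal angles
20–60°). Simulated "manual" raters apply multiplicative Gaussian noise to
the ratio indices (`truth · (1 + ε)`, `ε ~ N(0, cv²)`, default cv 0.05 —
a realistic inter-observer coefficient of variation for diameter ratios)
and additive noise `N(0, (cv·45°)²)` to the angle, clipped to [0°, 90°].
Pseudo-CT volumes assign each structure a constant HU-like intensity
(e.g. contrast-filled aorta 380, lung −780) plus Gaussian noise of SD 20.

**What passing tests do and do not show.** Phantoms prove that the geometry
recovers known truth to within rasterization error, that tie-breaks and
conventions behave exactly as documented, and that the statistics are
correct. They do not emulate partial-volume blur, contrast heterogeneity,
crescent-shaped right ventricles, septal bowing, motion, or segmentation
failure modes of real networks — agreement numbers on phantoms are an upper
bound on, not an estimate of, clinical performance.

## The toy segmentation stage

A compact U-Net (encoder/decoder with skip connections; two 3×3
convolution + ReLU blocks per resolution level, 2×2 max pooling, nearest
upsampling, skip concatenation, 1×1 classification head) is implemented
natively in R with im2col convolutions and hand-written backpropagation,
verified against finite-difference gradients in the test suite. Inputs are
three stacked adjacent axial slices (edge slices replicated), so the network
sees superior and inferior context; labels are the center slice.

The default configuration mirrors a conventional full-scale recipe
(512 × 512 × 3 inputs, 100 epochs, learning rate 10⁻⁵, depth 4, base 32
channels). The exercised configuration is deliberately tiny — 64 × 64
phantom slices, depth 2, base 8 channels, 20 epochs of Adam at 3·10⁻³ with
combined cross-entropy + soft-Dice loss on five phantom volumes (four
training, one validation) — sized so the whole chain trains in about a
minute on one CPU while still reaching high per-structure Dice on the
piecewise-constant phantoms; the combined loss and small batches matter here
because background and lung dominate the class distribution. The checkpoint
returned is the epoch with minimal validation loss. Predicted volumes are
ordinary labeled volumes and flow into `compute_indices()` unchanged; at
2.8 mm pixels a one-pixel boundary error already moves a ratio by several
percent, so toy-scale index errors are dominated by quantization.

## Numerical choices and degenerate inputs

- Tie-breaks: slice → lowest z, chord row → lowest y, extreme pixel →
  lowest x; max-pool ties take the first candidate in a fixed order. Every
  path is deterministic; two runs on the same input are bit-identical.
- Missing structures raise classed `structure_absent` errors naming the
  structure, slice and (from `compute_indices()`) the index that failed;
  the CLI maps data errors to exit code 1 and configuration errors to 2,
  and `--skip-errors` degrades batch runs to warnings.
- Degenerate septum configurations (coincident centroids, fewer than two
  closest-point midpoints, coincident midpoints) are errors rather than
  arbitrary lines.
- NIfTI headers store spacing as float32; spacings are snapped to 6
  significant digits on read so write→read round-trips typical mm spacings
  exactly; labels round-trip bit-exactly.
- Ratios use `dx` only and are spacing-independent; the angle uses both
  in-plane spacings.
- Problem sizes in the shipped validation: 200 random masks for the chord
  oracle, 50 phantoms for ground-truth recovery, 100 random tables plus a
  2000-subject simulation for the ICC, 30 phantoms for the end-to-end
  agreement run, 5 toy volumes for the segmentation chain — small enough to
  run routinely, large enough that the acceptance quantities are stable
  across seeds.

## Known limitations

- The measurement definitions are specific to axial acquisitions; no
  short-axis reformatting or four-chamber view estimation is attempted, and
  no clinical dysfunction thresholds are applied.
- The "upper and lower endpoints of the lung segmentation" are taken as the
  anterior/posterior extremes of the axial slice; with unusual lung
  morphology (large bullae, effusions) this axis may deviate from the true
  spinal direction.
- DICOM ingestion, resampling and registration are out of scope; convert to
  NIfTI first.
- The bundled network is a functional miniature for end-to-end testing, not
  a clinical segmentation model.
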
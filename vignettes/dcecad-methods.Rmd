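---
title: "Methods: automated lesion detection in breast DCE-MRI"
author: "dcecad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated lesion detection in breast DCE-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcecad)
```

## The problem and the model

Dynamic contrast-enhanced MRI acquires one pre-contrast image ("Phase 0")
and a series of post-contrast phases roughly 70 s apart. Enhancing lesions
— benign or malignant — take up the gadolinium agent early, so they appear
bright in the subtraction images `I_s(k) = max(phase_k − phase_0, 0)`.
Their *time–signal intensity curves* (TICs) then diverge: persistent
curves keep rising (typical of benign lesions), plateau curves level off,
washout curves fall again (both associated with malignancy). The pipeline
implemented here deliberately uses only the second and third post-contrast
subtraction images: by that time every enhancing lesion, whatever its TIC
class, is near its early maximum, while delayed phases would bias the
candidate set toward slowly enhancing benign tissue.

The detection model is intentionally simple and transparent: a lesion is a
connected region that (a) falls into the brightest of five Otsu intensity
classes in *both* early subtraction images, (b) is at least 15 px in area
and not vessel-like in shape, and (c) has Phase-0 texture/contrast features
that a trained classifier distinguishes from matched healthy tissue on the
contralateral breast. No inter-phase registration is attempted (the prone
position and the ~140 s window keep motion small; a 1-px mask dilation
absorbs the residue), and no benign/malignant discrimination is performed.

## Stage-by-stage choices

**Cropping.** Bounds are scanned on the unit-normalized Phase 0 image
against a background level of 0. MR air background is near-zero after
normalization; for real data with a noise floor, `estimate_background()`
(median of the four 8×8 corner patches) can be passed instead. The chest
depth is anchored at the lower-median column for even widths, and the
posterior margin is 10 px (6.5 mm at the 654.762 μm/px reference
resolution), clamped at the image edge. Subtraction happens on the raw
intensity scale and each cropped subtraction image is normalized to [0, 1]
afterwards (subtract-then-normalize), so the normalization constant cannot
leak information between phases.

**CLAHE with exponential target.** Each cropped subtraction image is
equalized per 8×8-tile histogram (256 bins) toward a truncated exponential
distribution on [0, 1] with decay α = 0.4; histograms are clipped at 1% of
the tile pixel count with uniform redistribution of the excess, and pixel
mappings are bilinearly interpolated between the four surrounding tile
look-up tables (clamped at the borders). The exponential quantile map is
`y = −log(1 − P·(1 − e^{−α}))/α`, which sends cumulative probability 0 to
0 and 1 to 1 and is strictly monotone, so per-tile intensity order is
preserved. A constant image maps to a constant.

**Alternating sequential filter.** Grayscale opening then closing with
Euclidean disks of radius 1 then 2 (`disk_kernel(r)` is the exact set
`dx² + dy² ≤ r²`; radius 1 is the 4-neighbour cross). We read "two
sequential openings and closings with increasing disks" as two open–close
pairs; radii (1, 2) are the smallest increasing pair and respect the 15-px
minimum lesion size downstream — a structure must be roughly 5 px thick to
survive the radius-2 opening, which is exactly what the size rule keeps.

**Multilevel Otsu.** Four thresholds / five classes, on a 256-bin
histogram of the unit-range filtered image. Maximizing between-class
variance is equivalent to maximizing `Σ_k w_k μ_k²`, which is additive over
classes, so dynamic programming over class boundaries finds the *exact*
global maximizer in O(bins² · classes); the test suite verifies equality
with exhaustive search over all threshold 4-tuples on 16-level images.
Empty classes are forbidden (−∞ in the DP), constant images and images
with fewer distinct levels than classes raise errors. The top-class mask
uses a strict inequality: ties at the threshold fall to the lower class.
Thresholding happens on the cropped region only — cropping precedes
thresholding in the pipeline order, and including thorax background would
distort the histogram.

**Rules.** Area < 15 px rejects, eccentricity > 0.95 rejects; both
boundary values keep, matching the strict wording of the thresholds.
Eccentricity comes from the ellipse sharing the component's central second
moments, with the +1/12 pixel-extent correction, so a single pixel is a
circle (0) and a 1×n line approaches 1; a 4:1 elongated structure crosses
0.95. The 15 px ↔ 10 mm conversion treats 15 px as a length at the
reference resolution; since the rule is applied to the *area*, an optional
`min_max_dimension` exposes the length reading. Components are 8-connected
by default (configurable).

**Control ROIs.** Reflect the kept mask about the real-valued midline of
the cropped frame, then about the vertical line through the mirrored
region's own centroid. Two reflections about parallel vertical axes
compose to a translation by `2·(midline − centroid_col)`; because the
rounding applies a single constant offset to integer columns, the
pixelwise construction is injective and conserves the pixel count exactly
(property-tested on random masks). On synthetic data the radiologist's
visual check is replaced by an overlap test against the truth lesions,
with up to 10 random row jitters of ±3 px before a conflicted control is
skipped with a warning.

**Features.** All 14 features are computed on Phase 0, on the 1-px-dilated
mask. GLCMs are accumulated from pixel pairs that both lie inside the mask
(not the bounding box: surrounding tissue must not contaminate the
statistics), after quantizing the in-mask intensities to 8 levels over
their min–max range; symmetric matrices, distances 1 and 2, the four
standard directions averaged per distance (which makes the statistics
invariant under 90° rotations — asserted in the tests). Entropy is in
bits. A constant ROI has undefined correlation, reported as 0 with a
warning. The ring for the contrast ratios grows the dilated mask by a 4-px
disk (the typical area-to-perimeter ratio of the detected lesions) and
subtracts it. The count of 14 = 12 GLCM + CON + C; the ROI mean and
standard deviation are available as optional extras (off by default) so
the default vector length matches the design figure of 14.

**Selection.** ReliefF with m = n sample iterations and k = 10 neighbours
per class, Manhattan distance on min–max-scaled features; weights are the
usual hit/miss mean-difference balance, prior-weighted across miss
classes, and lie in [−1, 1]. Backward elimination wraps a Gaussian-kernel
SVM (fixed default hyperparameters) in stratified 5-fold CV with the fold
assignment fixed by seed; at each step the feature whose removal least
hurts (most helps) the misclassification rate is dropped, removal
continues while the criterion does not increase, and stops when every
removal strictly worsens it. The non-strict rule is what makes redundant
duplicates removable (their removal leaves the criterion unchanged); the
trade-off is that on perfectly separable data the subset can shrink
aggressively. The greedy path is validated against exhaustive subset
search on six features with a deterministic leave-one-out 1-NN criterion.

**Classifiers.** The feed-forward network has one hidden layer (6 or 10
tanh units), two tanh outputs with prediction by the larger output,
mean-squared-error loss, and full-batch nonlinear conjugate-gradient
training in 25-iteration cycles with early stopping after 6 cycles without
validation improvement (max 1000 iterations). Each of the 5 repeats draws
a fresh stratified 65/15/20 train/validation/test split; metrics are
reported per repeat and pooled. The SVM uses a Gaussian kernel with γ and
cost tuned on an inner 3-fold grid (γ ∈ {0.25, 1, 4}/p, cost ∈ {1, 10});
SMOTE balances each outer training fold only — synthetic minority points
interpolated toward one of 5 minority neighbours never reach a validation
fold, avoiding the optimistic leak of oversampling before splitting.
Training-fold rows are put in a canonical content order before SMOTE and
fitting, which together with content-keyed fold assignment makes the CV
metrics invariant to the order samples arrive in. ROC/AUC uses the
trapezoidal rule, identical to the tie-corrected Mann–Whitney statistic.

**McNemar comparison.** Discordant counts b (SVM right, network wrong) and
c (the reverse) are Binomial(b+c, ½) under the null. The exact-conditional
one-sided p is `P(X ≥ b)`; the mid-p variant takes the tail beyond b plus
half of `P(X = b)`; an asymptotic normal variant is included for
completeness. With b + c = 0 the test is degenerate and reports p = 1 with
a warning. Comparisons run on the network's first held-out test split,
where the SVM's out-of-fold predictions are also honest held-out
predictions for the same samples.

## The phantom: what it emulates, what it does not

`generate_phantom()` builds a 256×256 slice: two half-disk breast
cross-sections (radius 17–21% of the image height) attached to a flat
posterior thorax band, with the air background exactly zero. Lesions are
ellipses whose minor axis stays above ~5.6 px for rule-size lesions
(masses are roundish; thin elongated shapes are the vessels' role), with
per-lesion amplitudes drawn from U(0.5, 0.75)·unit and piecewise-linear
kinetic curves: persistent rises fast then keeps rising strictly
(0.85·min(p/2, 1) + 0.15·p/6), plateau reaches its maximum at phase 2 and
holds, washout peaks at phase 2 and falls by 15% per phase. Vessels are
gently wobbling curves dilated to ~3 px width (eccentricity > 0.95 by
construction); the cardiac confounder is a strongly enhancing ellipse deep
in the thorax whose anterior rim enters the cropped frame through the
10-px posterior margin, exactly the partial-inclusion case the crop design
tolerates. Healthy parenchyma enhances mildly (≤ 0.12·unit) on a smooth
random field. Gaussian noise (sd 0.01 of the unit scale) is added to body
tissue only.

The benchmark (`generate_benchmark()`) derives per-slice seeds from one
master seed and cycles lesion target sizes through {12, 28, 45}, {10, 35,
60}, {14, 25, 50} px with cycling kinetic classes, so every slice carries
one sub-15-px lesion (which the rule stage must reject) and the sizes span
10–60 px deterministically for any seed.

What the phantom does *not* model: MR acquisition physics (Rician noise,
coil sensitivity profiles, bias fields, k-space artifacts), patient
motion, anatomical variability of real parenchyma, and partial-volume
effects. Passing tests therefore demonstrate that each algorithmic stage
does what it claims under controlled conditions with known truth — not
that the pipeline achieves any particular clinical sensitivity. The
Phase-0 contrast between phantom lesions and mirrored healthy tissue is
deliberately subtle, so the classification-stage metrics on the phantom
are modest by design; the classifier implementations themselves are
validated separately on synthetic feature clouds of known separability
(`simulate_feature_clouds()`, whose class means differ by 4 within-class
standard deviations per feature — effectively linearly separable, making
the recovery bounds seed-robust).

## Problem sizes and determinism

The default study conditions are a 20-slice benchmark (60 lesions, of
which 40 at or above rule size), 5 network repeats, 5 CV folds, and n =
400 for the feature-cloud recovery checks — sizes chosen so the full suite
and the acceptance script each run in well under a minute on one CPU while
every stage still sees a meaningful sample. All randomness flows from a
single integer seed through deterministic per-component seed derivation;
the same seed yields byte-identical artifacts (asserted in the tests).

## Known limitations

* Distribution-targeted CLAHE leaves several parameters open (tile grid,
  clip limit, α); our defaults (8×8, 0.01, 0.4) are the common toolbox
  conventions and are exposed in `cad_config()`.
* "Two sequential openings and closings" admits two readings; the
  open–close pair reading is implemented.
* DICOM ingestion is not provided (no DICOM reader in the R dependency
  stack); NIfTI and a plain-text CSV dialect are, and the default pixel
  size of 654.762 μm/px is assumed with a warning when a header carries
  none.
* The rotation-assisted variant of the crop-window search mentioned as a
  refinement of the original scheme is not implemented; the literal
  four-step scan is.
* Labels in synthetic mode come from truth-mask overlap (≥ 50% of the ROI
  on lesion tissue); on real data that step is a radiologist's call.
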
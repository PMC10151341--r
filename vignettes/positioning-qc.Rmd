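---
title: "Methods: automated breast-positioning quality control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated breast-positioning quality control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mammoqc` grades breast positioning on mediolateral-oblique (MLO)
mammograms against two technical criteria: whether the inframammary fold
(IMF) is imaged, and whether the nipple appears in profile. Each criterion
is graded on the three-level scale used in Japanese screening guidance
(1 = poor, 2 = average, 3 = excellent). The pipeline has two halves:
rule-based detection of the region each criterion lives in, and a learned
three-class grader on the detected patch. This vignette documents the
model, its assumptions, the parameters that matter, and the choices made
where the design was genuinely open.

## Canonical image frame

All detection logic assumes one orientation: **chest wall along the right
image edge, nipple pointing left-down**. `standardize()` mirrors
left-laterality images about the vertical axis, stretches to the working
size, and min–max normalizes intensities onto integer 0..255. Choices made
here:

* **Working size.** The full-resolution frame is 2730 × 4096 (width ×
  height). Resizing stretches to exactly that shape with no
  aspect-preserving padding — the detectors only use bottom-anchored and
  contour-relative geometry, which a monotone stretch preserves. Bilinear
  interpolation by default; nearest-neighbour is available and makes
  standardization exactly idempotent, which the test suite exploits.
* **Coordinates.** 1-based, row-major, origin top-left, and ROI boxes are
  closed intervals `[row0, row0 + h - 1]` — the indexing convention of R
  itself and of every matrix operation in the package. (An equivalent
  0-based, half-open formulation exists; we deliberately use the R-native
  one everywhere, including in sidecar JSON.)
* **Normalization.** Min–max on each image's own range, not on the
  bit-depth ceiling, so 16-bit and 8-bit sources land on the same scale. A
  constant image has no dynamic range and is rejected as degenerate rather
  than silently zeroed.
* **Laterality.** Taken from metadata or the file name; if unknown, the
  brighter image half decides (the breast is far brighter than background).
  An exact tie is an error, not a guess.

## IMF detection: bottom-up window scan

A square window (side `roi_size`, 256 px at full scale) starts flush with
the image's bottom edge, anchored at the chest-wall (right) edge, and moves
upward in steps of `scan_stride`. At each position the window is binarized
at a **global normalized threshold of 0.8** (strictly greater — pixel 204
of 255 is background, 206 is foreground) and the scan stops at the first
window where foreground exceeds **a quarter** of the window area (again
strict: `count > area/4`). That window is cropped as the IMF patch.

Open parameters and how they were fixed:

* **Stride.** The scan is defined position-by-position; a stride of 16 px
  trades an at-most-15-px localization offset for a 16× speedup. The
  stride-16 result is tested to stay within one stride of the exhaustive
  stride-1 scan.
* **Column anchor.** The fold sits at the junction of breast and chest
  wall, which under the canonical frame is the right edge; `"center"` is
  available for other conventions.
* **Non-convergence.** If the window reaches the top without meeting the
  criterion (no fold imaged — typically a poor-grade image), the topmost
  window is returned flagged `converged = FALSE` with a warning, rather
  than erroring: downstream grading can still consume the patch, and the
  pipeline logs the count.

## Nipple detection: segmentation and extrema

The chain is median denoise → binarize → morphological clean → border mask
→ largest component → left-bottom extremum:

* **Median filter**, 3 × 3, exact medians, reflect padding at borders. The
  3 × 3 path is a vectorized selection network; any odd size is supported.
* **Binarization** defaults to Otsu's threshold. (The 0.8 global threshold
  is an IMF-stage constant; nothing pins the segmentation threshold, and a
  data-driven one is robust to exposure differences. A fixed threshold
  remains available.)
* **Morphology**: opening then closing with a disk of radius 5 px, which
  removes radiopaque labels/markers thinner than the disk and fills
  comparable holes. Shape and radius are unreported territory; a disk is
  the isotropic default and 5 px at full resolution is small relative to
  any nipple bump worth detecting.
* **Border mask**: scanned mammograms carry bright shading bands along the
  edges; a rectangular mask zeroes `floor(0.02 × dimension)` pixels per
  side. 2% clears typical shading without touching the breast.
* **Largest component** under **8-connectivity** (breast contours are
  diagonal-heavy; 4-connectivity fragments them). Implementation: a
  compiled 4-connected labeling pass, then a union-find merge of label ids
  that touch diagonally — exact 8-connectivity at raster-scan cost. Ties in
  component size break toward the component first met in row-major order.
* **Left-bottom extremum**: among pixels attaining the component's minimal
  column, the one with maximal row — the lower of the two leftmost boundary
  points in the 8-point compass convention, which is where an in-profile
  nipple sits in this frame. Note the discrete consequence: on a smooth
  convex contour the minimal-column pixels form a short vertical chord, and
  the rule picks the chord's *bottom*, a few pixels below the tangent
  point. The phantom's ground truth is defined by the same rule, so
  recovery is measured against a consistent target.
* The ROI is **centred** on the extremum and clamped into the image.

## CLAHE

Detected patches are enhanced with contrast-limited adaptive histogram
equalization before grading: 8 × 8 tiles, 256 bins, normalized clip limit
0.01 (i.e. each tile histogram is clipped at 1% of the tile's pixel count),
bilinear blending between tile mappings. The parameters are unpinned by any
constraint stronger than common radiographic practice and are exposed in
`clahe_config()`. Patches whose dimensions are not tile-divisible are
reflect-padded for the transform and cropped back. Constant patches are
returned unchanged — there is no contrast to redistribute. CLAHE is applied
to the cropped patch (not the full image): enhancement then adapts to local
fold/nipple contrast rather than to breast-wide structure.

## Phantom generator

`generate_phantom()` renders the structures the detectors key on, with
exact ground truth: dark background (0.05 normalized), a half-elliptical
breast against the chest-wall edge (centre ≈ 0.52 of height, semi-axes ≈
0.58 width / 0.33 height, ±2% seeded jitter), a pectoral wedge (0.72), an
optional nipple bump on the contour apex, an optional bright fold band
near the breast's bottom row, an optional radiopaque label block, border
shading strips, and additive Gaussian noise (σ = 0.02). Labels are encoded
structurally:

| grade | fold band | nipple bump |
|---|---|---|
| excellent (3) | 2.4% of height tall, intensity 0.95 | radius 1.3% of height |
| average (2) | 1.0% tall, intensity 0.85 | radius 0.8% of height |
| poor (1) | absent | absent (off-profile) |

An excellent band at 0.95 binarizes above the 0.8 threshold and is thick
enough to trip the quarter rule; the average band is too thin to trip it —
so scan convergence itself carries grade information, as it should. The
default image is 1024 × 682, a ¼-scale of the full frame with `roi_size`
64, chosen so the whole cross-validated suite runs in minutes; geometry is
relative, so full-scale rendering is just a different `image_shape`. The
default class mix of `generate_dataset()` (0.75 / 0.16 / 0.09) mirrors the
heavy imbalance of screening data, where most images fail at least one
criterion. What the phantom does **not** model: glandular texture,
vasculature, calcifications, scanned-film grain, dose physics. Passing
tests therefore demonstrate that the algorithms implement their definitions
and recover truth under controlled geometry — not clinical performance.

## Classifier

The grading head is softmax over three classes; probabilities are computed
with max-subtraction and sum to 1 within 1e-6, giving a continuous quality
index alongside the argmax label. Probability ties resolve to the *lower*
grade — for quality control, the conservative direction.

The bundled backbone is a deliberately small CNN: one 3 × 3 convolution
(8 filters, ReLU), 4 × 4 average pooling, a dense layer to 3 logits,
softmax. It consumes 64 × 64 patches (anything else is resized bilinearly)
and trains with Adam (learning rate 1e-3), batch size 16, categorical
cross-entropy, a fixed maximum of 50 epochs and no early stopping; training
and initialisation are seeded. It is implemented with plain matrix algebra
(im2col convolution), trains in seconds on a CPU, and exists to make the
pipeline testable end to end. Tokens for ImageNet-scale backbones (VGG16,
Xception, …) are recognised but refused at run time: no pretrained weights
ship with the package, and nothing in the test suite depends on them.

## Evaluation

`make_folds()` partitions indices into k = 5 folds, sizes within one of
each other, stratified by class by default (per-class counts per fold also
within one) so every training split contains all classes — with 3-class
training this is the difference between a defined and an undefined run.
`cross_validate()` trains on k−1 folds, predicts the held-out fold, and
**sums** the per-fold confusion matrices into one 3 × 3 table. From it,
accuracy is trace/total, and recall/precision/F1 are **macro-averaged**
(unweighted mean of per-class values): under heavy class imbalance micro
averaging collapses onto accuracy, while macro exposes minority-class
behaviour — which is why reported recall/precision/F1 can sit far below
accuracy. Per-class ratios with zero denominators contribute 0 to the
macro mean (not NaN): an absent class scores zero rather than poisoning
the average.

## Numerical and degenerate-input conventions

* All comparators at named thresholds are strict (`>`), matching the
  "more than" phrasing of the stop rule.
* `floor(area/4)` is the quarter-rule comparison point, so a 256 × 256
  window needs ≥ 16385 foreground pixels to stop.
* Empty masks, constant images, missing classes, undersized images and
  malformed configurations raise classed conditions
  (`mammoqc_*_error`), never silent defaults.
* Every stochastic step (phantom rendering, label draws, fold assignment,
  weight initialisation, batch shuffling) is seeded, and `run_pipeline()`
  writes a manifest (config, seed, input/patch MD5 hashes) sufficient to
  reproduce a run byte-for-byte.

## Problem sizes used by the test suite

Property checks run at ¼ scale: brute-force oracle equivalence on 100
random instances per primitive (≤ 64 × 64), ground-truth recovery on 200
seeded phantoms, stride consistency on 50, fivefold CV learning sanity on
100 truth-located patches with a 20-seed balanced label-shuffle control
(45 patches, 8 epochs, 4 filters per run), and full-run byte
reproducibility on 10 images. These sizes were chosen as the smallest that
make the statistical assertions meaningful.

## Known limitations

* Only the MLO view and only the IMF / nipple-in-profile criteria; other
  positioning criteria (pectoral muscle angle, retromammary space,
  symmetry, craniocaudal view) are out of scope.
* DICOM is not read directly; convert to 16-bit grayscale PNG first.
* No patient-level grouping in cross-validation: folds are image-level.
* The tiny CNN is a pipeline-scale grader; clinical-grade accuracy would
  require pretrained backbones and real labeled mammograms, neither of
  which ships here.
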
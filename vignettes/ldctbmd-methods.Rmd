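---
title: "Methods: automated vertebral BMD measurement from low-dose chest CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated vertebral BMD measurement from low-dose chest CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its own methods: the model and
procedure each stage implements, the assumptions behind them, the defaults
and why they were chosen, and what the synthetic phantom does and does not
establish about behavior on clinical data.

## The measurement problem

Quantitative CT (QCT) estimates volumetric bone mineral density (BMD,
mg/cm³) of trabecular bone from calibrated CT numbers (HU). On a chest CT
the clinically reportable quantity is the mean BMD of L1 and L2, with T12
as a fallback reference when a lumbar vertebra is diseased or out of the
field of view. Automating QCT on screening chest CT requires three
non-trivial steps — finding vertebral bodies, naming them, and placing a
trabecular volume of interest (VOI) — followed by two trivial ones
(linear calibration, thresholding into bone-mass categories).

The pipeline treats these as separable contracts. Each stage consumes and
produces plain containers (`ct_volume`, `class_mask`, `instance_mask`,
`ellipse_voi`, `calibration_model`, `bmd_report`), so any stage can be
replaced or oracled out in tests. Indices are R-native: 1-based, with
inclusive slice ranges; slice 1 is the most superior (`read_volume()`
reorients NIfTI input to guarantee this, since the naming rules below are
meaningless without a fixed superior–inferior convention).

## Segmentation network

Voxel-level classification into four classes — background, T1–T6, T7–T12,
L1–L2 — by a 3D U-net whose convolutional stacks are dense blocks: layer
$j$ of a block receives the concatenation of the block input and all
previous layer outputs and emits a fixed `growth_rate` (default 8) of new
channels; a 1×1×1 convolution then reduces the concatenation to
`base_channels`. Dense connectivity keeps the 3D parameter count small
through feature reuse. Downsampling is 2×2×2 max pooling; upsampling is
nearest-neighbor; skip connections concatenate the encoder bottleneck
output into the decoder, followed by a 1×1×1 reduction. The head is a
1×1×1 convolution to 4 channels and a per-voxel softmax.

Design points that were genuinely open and how they were fixed:

* **Per-level dense-block depths** are not standardized for this
  architecture; the default `(2,3,4,4,4,3,2)` over a 4-level topology is
  config-exposed (`unet_config()`), and the test-scale configuration uses
  2 levels with `(2,2,2)`.
* **Downsampling** by max pooling rather than strided convolution — the
  classical U-net choice.
* **Loss**: soft Dice over the three foreground classes only, with
  smoothing $\varepsilon = 10^{-5}$:
  $\mathcal{L} = 1 - \tfrac13\sum_{c=1}^{3}
  \frac{2\sum_v p_{cv} t_{cv} + \varepsilon}
       {\sum_v p_{cv} + \sum_v t_{cv} + \varepsilon}$.
  Background is excluded because it dominates the voxel count.
* **Argmax ties** break to the lowest class index — deterministic.
* **Patch aggregation** at inference: overlapping sliding-window patch
  probabilities are averaged uniformly per voxel before the argmax; no
  Gaussian edge weighting.
* **Input normalization**: HU × 1e-3, so air is −1 and dense bone ≈ +0.4.

The forward pass, backward pass (verified against central finite
differences in double precision; exact to ≈1e-7 relative), Adam, and the
learning-rate schedule are implemented in the package on top of
RcppArmadillo GEMM kernels. Convolution is evaluated as 27 shifted
matrix products in single precision — the standard working precision for
CNN training — while everything crossing the R boundary is double.

Training uses Adam at initial learning rate 1e-4 (default; the
test-scale runs below use 1e-3, appropriate for the much smaller
network), halved whenever the monitored Dice metric fails to improve for
3 consecutive epochs (`lr_schedule()` is a pure function of the metric
history, so the contract is testable in isolation). The monitored Dice is
validation Dice when a validation set is given, else training Dice.

## Preprocessing

Axial slices are rescaled to 2 mm × 2 mm by separable bilinear
interpolation with pixel-center alignment (masks: nearest-neighbor, so
labels stay integral); the z axis is never resampled. Slices are cropped
to 160 × 160 about the body center, found as the centroid of the largest
connected component above −200 HU — a threshold that separates soft
tissue from air robustly; it is config-exposed. Crops record their offset so masks back-project exactly.
Patch sampling slides a 64-slice window down the volume with a clamped
final offset so the union of slabs covers every slice (stride > depth is
rejected, as it would violate that postcondition). Augmentation applies
the same random in-plane translation (±8 voxels) and rotation (±10°) to
image (bilinear) and mask (nearest); the magnitudes are conventions of
this package and recorded in config.

## Anatomical labeling

Vertebrae in 1-mm chest CT do not touch, so instances are recovered as
26-connected components of the binarized foreground (26 rather than 6 so
oblique cortical voxel chains do not split a body). Components under
`min_voxels = 100` (≈0.4 cm³ at 2×2×1 mm) are speckle and discarded.
Each instance takes the majority class of its voxels and the list is
sorted superior→inferior. Naming: class-3 instances become L1, L2 top-down;
thoracic instances are named bottom-up from the most inferior one as T12.
Extras beyond the anatomical range (a 13th thoracic, a 3rd lumbar) are
flagged unnamed rather than force-fitted — the realistic failure mode
being an over-segmented class yielding 13 thoracic candidates. When no
lumbar instance exists the bottom-up rule still anchors the lowest
thoracic instance as T12, flagged low-confidence, because the true
inferior extent of the field of view is then unknowable from the mask.

## Trabecular VOI geometry

The VOI is a 9-mm-high cylinder of identical axial ellipses centered on
the vertebral-body region of the middle slice
(`z_mid = floor((z_min + z_max)/2)`; a vertebra spanning fewer slices than
the cylinder is an error naming the instance). Sizing is by two ratios:
ellipse area = 30 % of the middle-slice region area, and short semi-axis
= 20 % of the region's *maximum row length*, with the long semi-axis
inferred from the area. Two interpretation choices, both config-exposed:
the sizing rule applies to **semi**-axes, and "maximum row length" is the longest
contiguous run of region pixels within a single image row, converted to
mm (so the ratios are scale-invariant identities; semi-axis lengths in mm
follow the pixel spacing). The ellipse is axis-aligned to the image grid —
the row-based sizing rule implies grid alignment — with the short axis
along the anterior–posterior (row) direction. Voxel membership uses voxel
centers, no partial-volume weighting: exactly testable and faithful to how
integer VOIs behave in QCT tooling. If the inferred long semi-axis comes
out shorter than the short one (degenerate, very elongated regions), the
axes are swapped and flagged; an ellipse escaping the region's bounding
box flags a warning (non-convex region). Basivertebral-vein avoidance,
done manually in interactive QCT, is not modeled — the centered ellipse
with a 30 % area budget is the automatic surrogate.

These two ratios are *identities of the construction*:
$\pi ab = 0.30\,A$ exactly and $a = 0.20\,W$ exactly, which is what
`scripts/acceptance.R` measures on a synthetic circular cross-section
(radius 50 voxels) and the suite sweeps over 200 random convex regions.

## Calibration and diagnosis

`BMD = slope · HU + intercept`, plain OLS on pooled target-vertebra pairs
(per-level fits are possible by subsetting; pooled is the default and the
standard practice). An externally calibrated
slope/intercept from QA-phantom scanning can be substituted
(`set_external_calibration()`) and takes precedence over a fitted model in
the CLI's config resolution. Categories: normal > 120, osteopenia 80–120
(both endpoints included, exactly as the printed intervals imply),
osteoporosis < 80 mg/cm³; "low BMD" pools the lower two. Negative BMD is
classified but flagged implausible. The report carries the L1–L2 average
as the standard metric and T12 as reference; with either lumbar vertebra
missing, no category is emitted and the report is flagged.

## Evaluation statistics

Dice `2|A∩B|/(|A|+|B|)` (both-empty defined as 1, flagged); per-level
Dice averages instances within a level, and "overall" is the mean of
per-level means. Labeling accuracy matches predicted to truth instances by
maximal voxel overlap; per-scan accounting is the default (one
correct/incorrect outcome per level per scan), which is how a single
failed scan among 40 yields 97.5 % at every level. Agreement combines OLS
of predicted on reference with Bland–Altman mean difference and 95 %
limits of agreement (mean ± 1.96·SD, n−1 denominator). AUC is the
Mann–Whitney pair probability with ties counted ½; the ROC curve is built
at every threshold between distinct scores, and the suite asserts
trapezoid-vs-pair-counting agreement to 1e-10 plus equality with an
independent implementation (pROC). ROC positivity direction: lower
predicted BMD ⇒ more positive (score = −BMD). AUC confidence intervals,
when requested, use a seeded stratified bootstrap (2,000 resamples by
default), documented here as the package's choice of CI method.

## The synthetic phantom

`generate_phantom()` emulates exactly the features downstream stages
consume, and nothing more: a straight column of 8–14 non-touching
elliptical-cylinder vertebrae (trabecular core of configurable mean HU per
vertebra, denser cortical shell, positive inter-body gap), inside a
soft-tissue body ellipse on air, with independent additive Gaussian voxel
noise. Identical specs (including seed) are bit-reproducible. Defaults
and their reasoning:

* spacing (1, 2, 2) mm — 1-mm slices are the assumption behind the 9-slice
  VOI and vertebra separability; 2-mm pixels are the network's working
  resolution.
* vertebral body 20 mm high, 4 mm gap, 15 × 18 mm semi-axes; cortical
  shell 0.8 mm (inside the anatomical 0.45–1.02 mm range) and 400 HU.
* trabecular HU: an even gradient 180 → 130 HU superior→inferior, spanning
  normal to low bone mass under the ground-truth calibration
  (slope 0.8 mg/cm³ per HU, intercept 0 — an arbitrary documented constant
  that makes truth and measured BMD commensurable; typical clinical slopes
  are of this order).
* soft tissue 30 HU, air −1000 HU, noise SD 15 HU (LDCT-like).

What the phantom does **not** model: beam hardening, streaks, scanner
kernels, ribs and posterior elements, degenerative change, fractures,
basivertebral veins, or anatomical shape detail beyond a convex
cross-section. Consequently, passing tests establish the correctness of
the geometry, calibration, naming logic, statistics, and the learnability
of the segmentation contract — not clinical-grade segmentation accuracy.
Clinical-scale accuracy claims for systems of this design require large
annotated patient datasets and are out of scope here.

## Test-scale training conditions

The learning-sanity check trains a 2-level dense U-net (growth 8, base 8,
blocks (2,2,2)) on 42 patches of 16 × 64 × 64 voxels cut from three
synthetic phantoms (4 thoracic + 2 lumbar vertebrae each, default noise),
30 epochs of per-patch Adam at initial learning rate 1e-3 with the
plateau-halving schedule, monitored on four validation patches from a
held-out phantom (`synthetic_training_set()`). Success is mean
**per-instance** Dice ≥ 0.80 on the held-out phantom: each true vertebra
against its maximal-overlap predicted component, class-agnostic. The
class-agnostic criterion matters: a 16-slice patch cannot see where it
sits along the spine, so the thoracic/lumbar class split is only weakly
identifiable from local context (in the phantom, mainly through the
attenuation gradient), while the foreground geometry itself is learned
essentially perfectly (observed ≈0.99 mean per-instance Dice). This run
takes roughly 13 minutes on one CPU; problem sizes were chosen as the
smallest that still exercise pooling, skip connections, dense blocks, the
schedule, and sliding-window aggregation together.

## Numerical notes and degenerate inputs

* Bilinear resampling reproduces constants exactly and affine ramps in the
  interior; rescaling at the current spacing is an exact no-op.
* `find_body_center()` on an all-air slice returns the geometric center,
  flagged, never an error.
* Volumes shorter than one patch yield a single air-padded patch, flagged.
* Bias-step ties in the LR schedule: "no improvement" is `<= best`,
  strictly-greater improves; the counter resets on every halving.
* Phantom generation validates that the column fits the volume and names
  the offending axis; specs with touching vertebrae (gap ≤ 0) are
  rejected at construction.
* All RNG consumption is seed-scoped (`with_seed`) and restores the
  caller's RNG state.

## Known limitations

Single-threaded CPU training is practical only at test scale; the
full-scale default configuration is provided for completeness, not speed.
Nearest-neighbor upsampling plus uniform patch averaging can produce
blocky boundaries that a transposed-convolution decoder would smooth. The
labeling stage inherits segmentation errors by construction (no
independent labeling model), and transitional anatomy (T13/L6) is out of
scope. DICOM import is out of scope; NIfTI is the interchange format.
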
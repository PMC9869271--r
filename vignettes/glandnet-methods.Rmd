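---
title: "Counting cotton pigment glands: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting cotton pigment glands: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pigment glands are dark, near-circular secretory structures, roughly
100–400 µm across, scattered densely over the leaves of glanded cotton.
Their density is a practical proxy for gossypol content, so breeders and
physiologists count them — historically by hand under a microscope, at a
cost of hours per leaf. In an RGB leaf image taken at roughly 45 µm per
pixel, one gland covers only a handful of pixels (about 2–9 px across),
sits among hundreds of neighbours, and competes with dark leaf-vein
shadows of very similar intensity. That combination — tiny objects, dense
packing, structured confounders — is what this package addresses.

`glandnet` implements the complete pipeline: a semantic-segmentation
network specialised for dense small objects, tile-based inference for
large images, shape-feature post-filtering, connected-domain counting
with density stratification, confusion-matrix evaluation, and a synthetic
scene generator that stands in for leaf data when none is available.

## The network

The model is an *inverted* U-Net, here called the interpolation–pooling
network. A standard U-Net contracts first: each pooling step halves the
map, and a 3-px gland shrinks toward a point before the decoder ever sees
it — exactly the features this task cannot afford to lose. The inverted
design enlarges first and contracts second:

* **Up path.** Two blocks of (3×3 same convolution → batch normalisation
  → ReLU) ×2 followed by ×2 nearest-neighbour interpolation take a
  120×120 RGB tile to 240×240 and then 480×480, with 16 channels after
  the first block.
* **Down path.** Two blocks of 2×2 max pooling followed by the same
  double-convolution structure return 480 → 240 → 120. Before each
  down-path convolution the pooled map is concatenated with the up-path
  feature map of matching resolution (16+16 = 32 and 32+16 = 48 input
  channels), fusing fine localisation with the aggregated context.
* **Head.** A 1×1 convolution to one channel and a rectifier produce a
  non-negative response map the size of the input; thresholding it gives
  the binary gland mask.

The printed description pins the spatial schedule (120 → 240 → 480 → 240
→ 120), "same" convolutions, the 16-channel first stage and
concatenation skips, but not every per-layer channel count; the
16/16/16 → 32 → 32 schedule used here is the smallest one consistent
with all of those statements, and `network_spec()` exposes it
(`base_channels`) rather than hard-coding it.

Choices the source leaves open, resolved as follows:

* **Initialisation** — He-uniform kernels, unit batch-norm scale, zero
  shifts, seed-controlled; building twice with one seed is bit-identical.
* **Inference-time normalisation** — batch statistics are frozen
  (running means/variances, momentum 0.1), so evaluation is
  deterministic and independent of batch composition.
* **Binarisation threshold** — the literal published rule maps every
  strictly positive rectified activation to foreground (`tau = 0`).
  Trained with mean squared error against {0, 1} targets the rectifier
  does drive background activations to 0, but any positive noise floor
  then becomes foreground, so `tau` is exposed and 0.5 — the midpoint of
  the target levels — is used for validation metrics and prediction by
  default.

## Training

Training follows the published recipe: mean-squared-error loss over
pixels, Adam, with defaults of 60 epochs × 250 steps × batch 2.
Unstated hyper-parameters take the canonical Adam values (step 1e-3,
β₁ = 0.9, β₂ = 0.999, ε = 1e-8). Batches are drawn uniformly *with
replacement* — 250 steps per epoch with thousands of training tiles only
makes sense as sampled steps, not full passes. There is no
learning-rate schedule and no early stopping; the checkpoint with the
best validation loss is retained. With the seed fixed, two runs produce
identical parameter trajectories.

The forward and backward passes are hand-written in single-precision
RcppArmadillo: convolutions are im2col + BLAS `sgemm`, the input
gradient of a zero-padded same convolution is computed as a same
convolution of the upstream gradient with the spatially flipped,
channel-transposed kernel, and a persistent trainer object keeps
parameters, Adam moments and all scratch buffers alive across steps so
the loop is bandwidth-bound rather than allocator-bound. Correctness is
established two ways in the test suite: an independent double-precision
reference implementation (plain R loops) must agree with the compiled
gradients to ~1e-6 relative, and that reference itself passes
per-parameter central finite-difference checks. (A note for anyone
extending the tests: *directional* finite differences fail here not
because the gradient is wrong but because batch-norm centring parks many
ReLU pre-activations exactly at the kink — e.g. the head bias at
initialisation — where the one-sided subgradient and a two-sided
difference legitimately disagree.)

## Tiling and stitching

Full leaves (e.g. 1600×1200) are processed as 100×100 cores, the same
unit used for density stratification. Predicting tiles independently
leaves seam artefacts, so each core is expanded to a 120×120 context
window, predicted, and trimmed back before stitching. The source
describes the 100 → 120 expansion but trims "4×5 pixels" at the edge,
which cannot reconcile with 120 − 100 = 20; the only symmetric,
seam-free reading is a uniform 10-px margin per side, which is what
`tile_grid()` implements (`stitch_tiles(crop_tiles(m, g), g)` is exactly
the identity, and the tests require it bit-for-bit). Context beyond the
image border is mirror-padded — zero padding would fabricate a dark rim
that looks like gland tissue. Images whose sides are not multiples of
100 are mirror-padded right/bottom and cropped back after stitching.

## Train/validation splitting

The 80/20 split is a uniform shuffle at whatever granularity the caller
passes to `split_dataset()`. The source does not say whether its split
was random by tile or grouped by leaf; random-by-tile is the default
reading used here, but splitting a vector of leaf identifiers instead of
tiles gives the leakage-aware, grouped split (tiles of one leaf never
straddle the boundary), which is the safer protocol when leaves differ
systematically.

## Post-filtering and counting

The binarised mask is cleaned by the re-implemented shape-feature filter:
connected domains (8-adjacency by default — a diagonally touching pair of
gland pixels is one gland) are kept iff their area lies in
[2, 938744] px. The lower bound removes single-pixel noise; the upper
bound is retained verbatim from the source even though it exceeds any
plausible gland — it is effectively "unbounded above". Only area is
filtered: roundness is mentioned generically in the source but never
given thresholds, so it is left as an extension hook.

Morphological closing (disk radius 1) is available and ON by default in
`filter_config()`, matching the published pipeline; it is computed
exactly, by embedding the mask in a zero frame before dilation/erosion,
so closing remains extensive and idempotent at image borders. Counting
workflows should know its documented failure mode: closing can fuse
glands separated by a single pixel into one domain (undercounting), and
the count-recovery tests therefore run with closing off.

Whole-leaf counts are taken on the stitched mask, so glands straddling
core boundaries are counted once; per-tile counts for density
stratification use the 100×100 cores.

## Evaluation

Pixel-level quality uses the confusion matrix: precision TP/(TP+FP),
recall TP/(TP+FN), F1 = 2TP/(2TP+FP+FN), and a two-class mean IoU,

$$\mathrm{mIoU} = \tfrac12\left[\frac{TP}{TP+FP+FN} +
\frac{TN}{TN+FN+FP}\right],$$

i.e. the average of foreground IoU and background IoU with the
background class's "true positives" being the TN pixels. The printed
mIoU equation reuses the TP symbol for every class; the class-swapped
reading above reproduces the published 0.8181 from the published
confusion matrix exactly, which validates the interpretation. Degenerate
denominators yield `NaN` plus a `degenerate` flag rather than errors.
The source also prints a pixel accuracy of 0.967 whose arithmetic from
its own confusion matrix gives 0.9708; this package reports the computed
value and does not chase the printed one. Counting agreement is the
squared Pearson correlation between automatic and reference counts
(matching the phrase "square of the correlation coefficient"), not a
regression-through-origin R².

## The synthetic scene generator

No leaf dataset was deposited, so the generator emulates the documented
imaging conditions and makes every downstream stage testable with known
ground truth:

* **Scale.** 100×100 px ≡ 4.5×4.5 mm (45 µm/px) — inferred, not stated;
  it reconciles the density-per-area definition with the 100–400 µm
  diameter statement, and is exposed as `um_per_px`.
* **Spots.** Dark disks, radius 1–5 px, intensity 0.05–0.25, placed by
  rejection sampling with a 2-px clearance so the ground-truth count
  provably equals the number of 8-connected mask components (an
  overlap-allowed mode exists for stress tests and is excluded from
  count-recovery checks). Placement is sampled *before* vein drawing, so
  the mask is a function of the seed and spot parameters only.
* **Density strata.** Counts per 100×100 reference area: < 40 (level 1),
  40–79 (level 2), ≥ 80 (level 3). The source says "less than 40" and
  "more than 80", leaving 40 and 80 unassigned; half-open bins assign
  boundary counts upward so the three bins partition all counts. Denser
  strata use smaller radii (1–4, then 1–3 px), which matches how crowded
  glands present and keeps non-overlapping placement geometrically
  feasible.
* **Confounders.** Dark curvilinear random-walk veins (drawn on the
  image, never the mask) and Gaussian pixel noise (sd 0.02).

What the generator does *not* emulate: illumination gradients from the
acquisition rig, specular leaf-edge artefacts, annotation noise (real
masks inherit human labelling errors), or the reflectance texture of
real tissue. Passing tests on synthetic scenes therefore demonstrates
that the machinery — architecture, optimisation, tiling, filtering,
counting — works as specified; they do not certify the published
real-leaf scores (accuracy 0.967, loss 0.0238, per-density R² of
0.97/0.94/0.91), which cannot be reproduced without the undeposited
images.

## Problem sizes

The package's own reduced experiment — used by the acceptance checks —
trains on 200 level-1 tiles of 120 px for 5 epochs × 100 steps at batch
2 (1000 tile-gradients) and evaluates on 50 held-out tiles. On these
scenes that is already deep into the plateau: validation F1 passes 0.95
within two epochs, and held-out counting r² exceeds 0.9. The full
published recipe (60 × 250 × 2) is the package default for real data.

## Known limitations

* The rectified-output + MSE combination is unusual by current practice
  (sigmoid + cross-entropy would be standard); it is kept because it is
  the published design, with `tau` as the robustness valve.
* Counting accuracy degrades when glands touch: neither the area filter
  nor closing can split a fused domain. This mirrors the documented
  adhesion failure mode and grows with density level.
* The trainer is single-threaded CPU code in single precision; it is
  sized for tile-scale experiments, not for training on large corpora.
* BMP support covers the camera's 24-bit uncompressed flavour only.
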
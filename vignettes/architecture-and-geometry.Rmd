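---
title: "Lightweight fruit detectors and RGB-D localization: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lightweight fruit detectors and RGB-D localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(jujubedet)
```

## The problem and the model family

Orchard fruit detection is dominated by two constraints: the objects are
small and heavily occluded, and the deployment target (an embedded
computer on a harvesting platform) bounds the parameter and compute
budget. `jujubedet` implements a family of single-class anchor-free
detectors organised around three structural substitutions to a YOLOv8n
baseline, each exposed both as a standalone operator and as a flag of
`model_config()`:

* **MobileViT backbone.** The C2f convolutional backbone is replaced by a
  MobileNetV2/MobileViT hybrid. The MobileViT block first encodes local
  structure (an `n x n` convolution, then a pointwise expansion to
  `d > C` channels), unfolds the `H x W x d` map into `P = wh` intra-patch
  positions by `N = HW/P` patches, applies a transformer *across patches*
  at each position (so global context is modelled with convolution-scale
  cost), folds back — preserving patch order and intra-patch pixel
  order — projects to `C` channels, and fuses with the input through a
  final `n x n` convolution. Unfold/fold are exact inverses; this is
  tested exhaustively.
* **LSK attention at P3.** The P3 neck scale (stride 8) carries the
  fine-grained features on which small fruit are found, and is where
  foliage clutter hurts most. The large-selective-kernel module grows the
  receptive field with a 5x5 depthwise convolution followed by a 7x7
  depthwise convolution with dilation 3, projects each context by 1x1
  convolutions, pools the stacked contexts channelwise (average and max),
  derives one sigmoid spatial mask per kernel from a 7x7 convolution on
  the two pooled maps, and multiplies the input by the fused masked
  context. Insertion after P3 is the default (`lsk_at = "P3"`); P4/P5 are
  available.
* **GSConv neck.** Dense stride-2 downsampling convolutions in the PAN
  path are replaced by a unit that computes half the output channels
  densely and half by a 5x5 depthwise convolution, then interleaves the
  halves with a channel shuffle (a fixed, self-inverse-for-two-groups
  permutation).

All eight combinations are buildable; `"mlg-yolo"` denotes the full
combination.

## Calibration of the canonical configuration

The published description of this architecture family fixes the block
types and insertion points but not the MobileViT stage widths, transformer
depths or feed-forward dimensions. The published budgets, however, are
precise: 3,011,043 parameters / 8.20 GFLOPs for the baseline and 1,173,429
parameters / 5.40 GFLOPs for the full variant at a 640x640 input. We
therefore treat those budgets as the specification of the missing
hyperparameters:

* The baseline, LSK and GSConv structures are fully determined — our
  builds reproduce the baseline count and the LSK (+11,334 at P3, C = 64)
  and GSConv (−89,760) deltas exactly, which also settles two structural
  ambiguities: the LSK fusion convolution is a biased 1x1, and the GSConv
  depthwise half uses a 5x5 kernel. The published totals include the
  head's fixed 16-weight distribution-focal projection, and we follow that
  convention.
* The MobileViT backbone was calibrated once against the full-variant
  count: stage channels 16/24/32/48/64, inverted-residual expansions
  2/4/4/4/4, transformer stages at strides 16 and 32 only (token dims
  96 and 100, three layers each, four heads, feed-forward widths 185 and
  297), one extra MV2 block at stride 8, and an SPPF hidden width of 31.
  This reproduces 1,173,429 exactly and lands at 5.41 GFLOPs.
* Placing a 2x2-patch transformer at stride 8 was rejected during design:
  at a 640 input its attention alone costs about 2 GFLOPs
  (`4PN^2d` multiply-accumulates with `N = 1600`), which no parameter
  setting reconciles with the published compute budget. The stride-8
  stage is therefore purely convolutional.
* The published per-variant counts are not mutually additive (they
  disagree by ~1.3k parameters), so no single configuration can reproduce
  every row. Anchoring to the full variant leaves residuals below 0.2% on
  the intermediate rows (backbone-only: 1,183,175 vs 1,181,307).

**FLOP convention.** `count_flops()` counts convolutions and matrix
products at two operations per multiply–accumulate plus bias additions;
normalisation, activations, pooling and elementwise ops are excluded (the
convention under which detector budgets are conventionally quoted). Under
it the baseline measures 8.08 G against the published 8.20 G (−1.4%), the
full variant 5.41 G against 5.40 G.

## Synthetic scenes

The generator emulates the statistics of the emulated capture conditions:
640x480 native frames, a handful to a few dozen quasi-elliptical fruit of
8–22 px radius, elongated leaf-shaped occluders of configurable opacity,
and a global illumination factor in [0.7, 1.3]. All ranges are
`scene_spec()` parameters; a seed fully determines the scene. Fruit whose
visible fraction (pixels not covered by an opaque leaf or a nearer fruit)
falls below 25% are excluded from the annotations — a configurable,
deliberately conservative stand-in for a human annotator's behaviour.
Brightness/rotation/translation augmentation ranges (±30%, ±15°, ±10%)
are likewise conventions, not published values.

What the scenes do *not* model: real foliage texture, specular
highlights, perspective foreshortening, camera noise, or the size/occlusion
joint distribution of a real orchard. Tests passing on synthetic scenes
therefore validate the *pipeline* — geometry, losses, decoding, metrics —
not field accuracy.

The split arithmetic follows the emulated protocol: an 8:1:1 random
partition with largest-remainder rounding, each split tripled by two
augmented copies per image (930 → 744/93/93 → 2,232/279/279). Because
augmenting validation and test data inflates evaluation optimism, the
tripling of those splits can be disabled (`augment_val_test = FALSE`);
the default reproduces the published arithmetic.

## Desk-scale training

There is no GPU deep-learning stack in scope, so the trainer runs exact
forward/backward passes in R (im2col + BLAS convolutions) on
reduced-width models (`width_mult = 0.25`) at 64 px inputs — sizes chosen
so the full suite runs in tens of seconds. The optimizer matches the
published recipe (SGD, batch 4, lr 0.01, momentum 0.937, weight decay
5e-4); the loss is a simplification of the baseline's composite loss:
binary cross-entropy on the class map plus distribution-focal regression
of the four box-side distance distributions, with each ground-truth box
assigned to the centre cell of the finest scale whose bin range fits it.
The task-aligned multi-cell assigner and the CIoU term of the full recipe
are omitted; the contracts the trainer must satisfy (monotone loss
decrease on a 20-scene smoke set; >90% self-mAP after overfitting 4
scenes) are tested, and analytic gradients are verified against central
differences at probes spread across stem, backbone, neck and both head
branches.

Two consequences of tiny batches are handled explicitly. Batch-norm
statistics come from single images during training, so at inference the
model defaults to the same per-map statistics (`norm = "instance"`);
exponential running averages remain available but diverge from the
training distribution on very small runs. And MobileViT transformer
stages are forward-only: `train_model()` refuses them with an informative
error rather than training a partially-frozen network silently.

## Detection decoding and evaluation

Raw head maps carry 4×16 distance-bin logits plus class logits per cell.
Decoding takes the softmax expectation of each side distribution, scales
by the stride, filters by confidence (default 0.25) and applies greedy
NMS (default IoU 0.45) with a deterministic tie-break (score, then area,
then index), making the result independent of input order. Boxes are
clipped to the frame; at inference on arbitrary sizes the image is
letterboxed and boxes are mapped back before reporting. The picking point
is the box midpoint, kept real-valued until the depth lookup rounds to a
pixel.

`average_precision()` sweeps the score-sorted precision–recall staircase
with greedy one-to-one IoU matching. The published protocol does not
state an interpolation, so both the raw rectangular sum and the all-point
interpolated envelope are exposed (interpolated is the default; the
cross-check against an independent brute-force integration uses the raw
form, which that construction computes). The IoU threshold defaults to
0.5 — the community convention for a single mAP figure, since the
published evaluation does not say whether 0.5 or 0.5:0.95 was used — and
a threshold vector is accepted for the averaged form. Zero-denominator
conventions: precision and recall are 0 when their denominators vanish.

## 3D localization geometry

A detection centre `(u, v)` plus a depth reading `z` deprojects through
the pinhole model (`x = (u - cx) z / fx`, `y = (v - cy) z / fy`), and the
camera-frame point is carried into the robot base frame by the hand–eye
transform: a w-first quaternion (normalised on input; `q` and `-q` are
the same rotation) turned into `R`, assembled with the translation into
the 4x4 affine `T`, applied to homogeneous coordinates. Depth maps are
millimetres internally (RGB-D camera convention); calibration units are a
mandatory tag, converted at the interface. A missing or non-positive
centre depth falls back to the median of valid readings in a 5x5 patch —
the published pipeline does not state its handling, so the fallback is
configurable and detections without usable depth are reported separately
rather than dropped. The whole chain is validated by a render-then-invert
oracle: a simulated pinhole camera renders depth for known base-frame
points, and the pipeline recovers them to 1e-6 of the scene scale with
noise-free depth. The physical millimetre-scale accuracy of a real arm
and camera is hardware-bound and out of scope; only the error statistics
(per-axis mean absolute error, standard error `s/sqrt(n)`) are
implemented and verified on closed-form cases.

## Numerical choices and degenerate inputs

* Weight init: He-normal for convolutions, unit/zero batch-norm, zero
  biases; all builds are seeded and bit-reproducible.
* Normalisation inside blocks is batch-norm + SiLU (the baseline's
  convention); the MobileViT pointwise expansion is a biased convolution
  without normalisation, and LSK convolutions are biased and
  normalisation-free, matching the parameter budgets above.
* Max-pool backward routes gradients to the first maximum on ties;
  NMS and matching tie-breaks are documented and deterministic.
* Degenerate inputs error early and explicitly: non-divisible patch
  shapes, odd GSConv widths, zero-norm quaternions, non-positive depths,
  empty training splits, ground-truth-free AP.

## Known limitations

Pure-R training does not scale beyond smoke tests; transformer stages are
forward-only; the synthetic scenes are a pipeline fixture, not a field
benchmark; and the FLOP figure depends on the stated counting convention,
as all such published figures do.
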
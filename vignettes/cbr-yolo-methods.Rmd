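---
title: "CBR-YOLO in cbryolo: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CBR-YOLO in cbryolo: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbryolo)
```

This vignette is the package's account of the science it implements: the
detector and its four bespoke modules, the loss, the weather model, how
the structural calibration was done, and what the synthetic-data tests do
and do not establish. Nothing stated here as an empirical result goes
beyond what the test-suite and `scripts/acceptance.R` themselves compute.

## The detection problem

The task is multi-object recognition of four cattle behaviours —
standing, walking, eating, lying — in outdoor photographs with occlusion
between animals and highly variable weather, under a hard constraint on
model size so the detector can run on farm-side edge hardware. The
package follows the single-stage anchor-free YOLOv8 recipe: a backbone
produces feature maps P3/P4/P5 at strides 8/16/32, a neck fuses them, and
a head predicts, at every grid cell, class probabilities and a
distribution-focal regression of the four box-side distances
(`reg_max = 16` bins per side, decoded by the expectation of the softmax).
Training assigns cells to ground-truth boxes by task-aligned matching
(classification score `^0.5` × IoU `^6`, top-10 cells whose centers lie
inside the box) and optimises

`loss = 7.5 · box + 0.5 · cls + 1.5 · dfl`

where `box = 1 − Inner-MPDIoU`, `cls` is binary cross-entropy against the
soft aligned targets, and `dfl` the distribution-focal cross-entropy on
the overlap-term distances. The gains and assigner constants are the
standard YOLOv8 values.

## The Inner-MPDIoU criterion

For a predicted and a ground-truth box in pixel corners, with `d₁²`, `d₂²`
the squared distances between the top-left and bottom-right corner pairs,

`Inner-MPDIoU = IoU(inner(pred), inner(gt)) − d₁²/(w²+h²) − d₂²/(w²+h²)`

`inner(·)` scales a box about its center by `ratio` (default 0.7, within
the 0.5–1.5 range in which the auxiliary-box construction is meaningful;
values below 1 concentrate the gradient on the box core, which helps with
the loose, deformable outlines of standing and walking animals). At
`ratio = 1` the measure reduces exactly to MPDIoU — the test-suite pins
this to 1e-12.

Two readings of the normaliser `w² + h²` circulate: the input-frame
dimensions and the ground-truth box's own dimensions. The package
defaults to the frame dimensions (the original minimum-point-distance
formulation) and exposes `mpd_norm = "gtbox"` for the box-diagonal
reading, so both are available. Where the verbal description of the loss
("IoU minus the portion outside the ground truth") and its equation
disagree, the equation wins; that is what is implemented.

The corner-distance penalties are deliberately *not* inner-scaled, and
the distribution-focal term regresses the true (unscaled) distances: the
auxiliary-box construction is scoped to the overlap term only.
Gradients of the measure with respect to the predicted corners are
analytic (the IoU subgradient chained through the center-preserving
scaling) and are verified against central finite differences at 1e-4
relative tolerance.

## The four architecture modules

**StarNet backbone.** A stem (3×3, stride 2) and four stages, each an
ordinary 3×3 stride-2 convolution followed by star blocks; widths double
per stage (`base_width · 1,2,4,8`). A star block is: depthwise 7×7 +
BatchNorm → two parallel 1×1 expansions (factor 4) → elementwise product
(ReLU6 on one branch) → 1×1 projection + BN → trailing depthwise 7×7 +
BN → residual add. The elementwise product is the point of the design —
a test replaces it with addition and checks the outputs diverge. P3/P4/P5
are the outputs of the last three stages.

**SPPF-LSKA.** Standard SPPF (1×1 halving, three serial 5×5 stride-1
max-pools, concatenation) with large separable kernel attention inserted
on the concatenated map — the richest features — before the final 1×1.
One textual description of the modified layer mentions two pools; the
package keeps the three-pool SPPF semantics (override `sppf_pools = 2`)
because the layer is described as a modification of SPPF and changing the
pool count would silently change the baseline comparison. LSKA default
`k = 11, d = 3`: kernels `1×5/5×1` plus dilated `1×3/3×1` (the dilated
length is `⌈k/d⌉` rounded **down** to odd so every kernel stays odd and
symmetric; with the default this makes the cascade's impulse-response
support exactly `k`, which the suite measures with an impulse probe).

**MCFP neck.** All three levels are aligned to `neck_width` channels by
1×1 convs. A top-down pass (nearest ×2 up-sampling, add, 3×3 refinement)
carries semantics down. The three paths are then fused at the stride-16
scale — the P3 path through ADown (average-pool context, channel split,
3×3 stride-2 conv ‖ max-pool + 1×1), the P5 path through up-sampling —
and passed through an inception-style context block (parallel depthwise
identity / 3×3 / 1×7+7×1 branches, summed, mixed by a 1×1, residual).
The context is then *diffused*: resampled to each level, projected by a
level-specific 1×1 and residually added. The published description fixes
the ingredients but not every edge of the wiring; this reading is
committed in one builder (`build_mcfp`) so alternates are swappable, and
the diffusion property itself — every backbone level influences every
neck output, including zeroed-out ones — is what the tests pin down, via
gradient probes rather than a particular wiring.

**LMFD head.** Per level: 1×1 conv + GroupNorm + SiLU (level-specific) →
3×3 conv + GroupNorm + SiLU with parameters shared across the three
levels → shared 1×1 regression (`4·reg_max` channels) and classification
(`n_classes`) convs, the regression output multiplied by a per-level
learnable scalar initialised to 1 (the FCOS-style Scale, which absorbs
the differing dynamic range of the three strides and is the reason the
deeper convs can be shared at all). GroupNorm rather than BatchNorm
keeps the head batch-size independent, which the suite checks by
comparing batched and single-image forward passes.

## Structural calibration and the accounting convention

The published description leaves the concrete widths open (backbone base
width and depths, neck width, head width) but prints hard structural
anchors: the assembled model at 1.40 × 10⁶ parameters and 5.2 GFLOPs,
the YOLOv8n baseline at 3.0 × 10⁶ parameters and 8.7 GFLOPs, the
baseline's decoupled head at 7.52 × 10⁵ and the LMFD head at 1.12 × 10⁵
(an 85% reduction). Calibration against those anchors is an explicit
build step of this package, with the count tests as its oracle.

Two findings fix the convention:

* The YOLOv8n graph implemented here matches the stock implementation
  exactly: 3,011,612 trainable parameters at 4 classes, and at 80 classes
  3,157,184 = the stock 3,157,200 minus the 16 frozen distribution-decode
  weights, which frameworks include in their totals and a *trainable*
  count excludes.
* Conv-only 2-ops-per-multiply-accumulate FLOPs at 640 px give 8.74 G for
  the **80-class** configuration and 8.09 G at 4 classes. The published
  8.7 (and the companion figures for the larger family members) are
  therefore stock-configuration profiles, while the parameter columns are
  4-class counts. The package adopts that mixed convention where it
  reports the baseline: parameters at the working class count, the
  baseline FLOP figure on the stock configuration.

With the head width solved in closed form against the 1.12 × 10⁵ budget
at the baseline's pyramid channels (64/128/256), `hidden = 86` lands at
111,699 parameters — an 85.1% reduction against 752,076, matching the
printed claim — with `gn_groups = 2` (the groups must divide 86). The
remaining widths were then searched against the two whole-model anchors:
`base_width = 18`, `depths = (1, 2, 4, 2)`, `neck_width = 80` give
1,397,173 parameters and 5.185 GFLOPs (2×MAC, 640 px). Where two printed
values for the same quantity conflict (the assembled model's FLOPs appear
as both 4.8 and 5.2), the value corroborated by the running text (5.2)
is the calibration target. Both FLOP conventions remain available:
`"table"` (2×MAC + bias adds; the convention detection models are quoted
under) and `"eq11"` (the per-layer formula
`Cin/g·Cout·Kh·Kw·Hout·Wout + Cout·Hout·Wout`, one op per MAC).

## Weather synthesis

A weathered image is the per-pixel convex combination
`I = J·t + A·(1 − t)` with transmittance map `t ∈ [0,1]` and atmospheric
light `A ∈ [0,1]` — so the output needs no clipping and is elementwise
between `J` and `A`, which is tested as an invariant. The published
method fixes this blending equation and the five kinds but not the
per-kind construction of `(t, A)`; the package's recipes are its own
design, each driven by a single `intensity ∈ [0,1]` chosen so the tests
are quantitative:

* fog: smooth low-frequency field with mean pinned to `1 − 0.6·intensity`
  (tested at ±0.05), `A ~ U(0.8, 1)`;
* rain / snow: `t` drops by `0.7·intensity` on randomly placed angled
  streaks / round flakes, `A ~ U(0.85, 1)` / `U(0.9, 1)`;
* sun flare: radial Gaussian falloff of `t` around a random center,
  `A = 1`;
* overexposure: spatially uniform `t = 1 − 0.5·intensity`, `A = 1`.

At `intensity = 0` every recipe degenerates to `t ≡ 1` (identity). One
kind is applied per image (the published examples show single-kind
panels); `weatherize_split()` augments a seeded random half of the
training set by default and *adds* the weathered copies rather than
replacing the originals — with only ~4,000 training images, discarding
clean originals would trade clean-weather accuracy for nothing.
Transmittance is depth-independent: no depth maps exist for this data,
so physically based depth-dependent haze is out of scope.

## Data handling choices

Labels are YOLO-format (class, normalized center-size), written at six
decimals; round-tripping is lossless at that precision. Pixel boxes are
continuous 0-based corners, IoU is computed on continuous areas. The
random split defaults to 8:1:1 with rounded sizes; the published split
counts deviate slightly from exact 8:1:1 because of a same-environment
grouping constraint that is not reproducible from the outside, so the
package splits i.i.d. and documents the ±1 rounding rule instead.
Augmentation implements the standard five transforms; magnitudes are not
published, so the defaults are the YOLO-ecosystem ones (HSV gains
0.015/0.7/0.4, noise σ up to 0.05 of the dynamic range, crop keeping
60–100% per dimension, min box visibility after crop 0.2). Mosaic is
deliberately not implemented: the published pipeline lists exactly five
transforms.

## The synthetic-scene generator

The generator is first-class, tested code: textured low-frequency
backgrounds and animal-like blobs with class-specific silhouettes
(standing = body on legs, walking = offset legs, eating = head lowered at
the front, lying = low flat ellipse), painted in arbitrary order so later
instances occlude earlier ones. With probability `occlusion_prob` an
instance is *constructed* to overlap its predecessor by 40–55% of the
smaller placement box — enough to exercise occluded assignment, while the
occluded animal stays substantially visible (real annotation practice
does not label invisible animals). Ground-truth boxes are tight around
the painted silhouette, which is what makes the augmentation-consistency
test possible: re-deriving a blob's box from transformed pixels must
match the transformed label within 2 px.

What passing tests on these scenes shows: the whole stack — assignment,
loss, gradients, decode, NMS, evaluation — is wired correctly and has
the capacity to fit multi-instance, partially occluded, four-class scenes.
What it does not show: robustness to real cattle appearance, real
backgrounds, real weather, motion blur, or dataset-scale variation. The
published accuracy figures on the cattle dataset are not reproducible at
desk scale and are not claimed; the structural numbers are.

## Numerical and training choices

* Image tensors are `(H, W, C, N)` double arrays on the `[0,1]` scale
  (the 8-bit range divided by 255).
* BatchNorm uses batch statistics in training with momentum-0.1 running
  stats (initialised to mean 0 / variance 1, so inference is
  deterministic even untrained); GroupNorm is per-sample throughout the
  head.
* Weight init is He-normal scaled by fan-in; the classification bias
  starts at the −log((1−p)/p), p = 0.01 cold prior and the regression
  bias at 1, the standard stabilisers for dense detection.
* Training is plain SGD: lr 0.01, momentum 0.937, weight decay 5e-4 on
  convolution weights only, batch 32, 640 px defaults; linear warm-up
  over 3 epochs then linear decay to 0.01·lr0. The epoch count is not
  published; the default is 300 for full runs. Everything is seeded:
  weight init, data order, augmentation. Two runs with one seed produce
  bitwise-identical first-epoch losses (tested).
* The desk-scale smoke configuration used by the suite is 8 synthetic
  96 px scenes, batch 4, 150 epochs — about two minutes on one CPU —
  chosen as the smallest setting at which the overfit check (train-set
  mAP@0.5 ≥ 0.9) is comfortably reproducible.
* Degenerate inputs: zero-area boxes yield IoU 0 with a warning; images
  without objects contribute only the background classification term;
  non-finite raw predictions abort training with a diagnostic rather
  than propagating NaNs.

## Known limitations

The engine is single-threaded and eager; it is sized for desk-scale
verification, not production training. mAP is reported at IoU 0.5 only.
The MCFP wiring and the per-kind weather recipes are committed readings
of designs whose published descriptions are partly pictorial; both are
isolated behind single builders so alternates can be swapped without
touching the rest of the stack. The reported single operating point for
precision/recall is the pooled-F1 maximiser, a documented choice where
the published operating point is unknown.
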
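---
title: "pestlite: models and methods"
author: "pestlite authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pestlite: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pestlite is a self-contained R toolkit for building, training, compressing
and evaluating lightweight one-stage anchor-free detectors for larval pests
of swallowtail butterflies in orchard imagery. Larvae appear in two visually
distinct stages — instars 1–3 ("young": brown, mottled, resembling bird
droppings) and instars 4–5 ("old": green, smooth, with small glandular
horns) — frequently occluded by leaves, branches and fruit, under front,
side and back lighting. This vignette documents the models, the numerical
choices, and what the bundled synthetic data can and cannot establish.

## The detector family

The baseline architecture is the standard YOLOX design: a CSPDarknet
backbone (Focus space-to-depth stem, CSP stages, spatial pyramid pooling),
a PAFPN neck, and decoupled heads that emit, at strides 8/16/32, per-cell
box offsets `(dx, dy)`, log-sizes `(log w, log h)`, an objectness logit and
per-class logits. `build_model(model_config("yolox-s"))` and friends
reproduce the reference variants exactly: enumerating all learnable tensors
(convolution kernels and biases, batch-norm scale/shift) gives 8,968,255 /
25,326,495 / 54,208,895 / 99,071,455 parameters for the s/m/l/x variants —
8.97 / 25.33 / 54.21 / 99.07 M, which round at one decimal to the widely
printed 9.0 / 25.3 / 54.2 / 99.1 M. `count_params()` is input-size
invariant; `count_flops()` reports both the `2·H·W·(C_in·K² + 1)·C_out`
convention and the multiply–accumulate count (half of it), because
published tables mix the two. At 640-px input the s/m/l/x variants give
26.75 / 73.64 / 155.47 / 281.67 G under the first convention (the s value
matches the widely printed 26.75 G to the last digit) and half that as
MACs; printed figures for the larger variants follow neither convention
consistently, so no single one is forced to agree.

The lightweight pest variant (`"pest"` preset) modifies this baseline in
four ways:

* **GhostNet-GE backbone.** Each CSP stage is replaced by a stack of
  Ghost-ECA (GE) bottlenecks. A Ghost module computes `n/s` channels by
  ordinary convolution and synthesizes the remaining `(s-1)·n/s` "ghost"
  channels with cheap 3×3 depthwise transforms; the cost ratio against a
  standard convolution is exactly `s·c/(c+s-1) → s`. We use the customary
  split `s = 2` and 1×1 primary kernels. Efficient channel attention (ECA)
  sits between the bottleneck trunk and the second (linear) Ghost module:
  global average pooling, a 1-D convolution whose kernel adapts to the
  channel count (`k = |log2(C)/2 + 1/2|` rounded to the nearest odd, ties
  up), and a sigmoid gate. The stage plan mirrors CSPDarknet's stride
  schedule so the neck interface at strides 8/16/32 is unchanged.
* **ASFF fusion.** After the PAFPN, each output level is replaced by an
  adaptively weighted blend of all three levels: non-target levels are
  compressed by 1×1 convolutions and resized (nearest-neighbour upsampling
  toward finer levels, stacked stride-2 3×3 convolutions toward coarser
  ones); per-position logits from 1×1 convolutions are softmax-normalized
  so the three weights form a simplex at every position. Fusion is applied
  to all three levels.
* **TS heads.** Head convolution blocks use the tanh-softplus activation
  `TS(x) = tanh(x)·softplus(x)` instead of SiLU (conv–BN–TS, "CBT").
  Softplus is evaluated as `max(x, 0) + log1p(exp(-|x|))` for stability.
  Activations carry no parameters, so swapping them never changes counts.
* **Soft DIoU-NMS.** At decode time, suppression uses distance-IoU
  (`IoU - ρ²/c²`, with ρ the center distance and c the enclosing-box
  diagonal) and decays, rather than deletes, the scores of boxes whose
  DIoU with the kept box reaches the threshold `N_t` (default 0.5):
  `S ← S·exp(-DIoU²/σ)`, compounding across iterations, with σ = 0.5 and a
  final floor of 1e-3 on decayed scores. The decay keeps heavily occluded,
  overlapping larvae recoverable. Suppression is per class; the signed
  DIoU is used exactly as defined (values below `N_t` take the identity
  branch anyway).

The base-variant sources are ambiguous about whether the enhanced design
starts from the x- or s-scale network, so depth/width are a configuration
axis: baseline counts are validated at s/m/l/x scale, and the pest presets
default to s-scale (`"pest"`) and a desk-scale `"pest-nano"` (depth 0.11,
width 0.125, 256-px input) used throughout the test suite.

## Training

Training is plain SGD with momentum 0.93 and weight decay 5e-4
(convolution kernels only), under cosine annealing
`η_t = ½(1 + cos(tπ/T))·η` where `t` is the optimizer step and `T` the
total step count — the only reading under which the published formula is a
schedule. The transfer recipe is two-phase: phase 1 freezes every backbone
parameter (defaults: 100 epochs, batch 32, lr 1e-3), phase 2 fine-tunes
everything (100 epochs, batch 16, lr 1e-4). Frozen batch-norm layers run
in inference mode. Classification targets use label smoothing 0.01
(`1 - ε + ε/K` / `ε/K`).

The loss is the standard anchor-free composite: an IoU term `1 - IoU` on
positives (weight 5), binary cross-entropy objectness over all cells, and
smoothed binary cross-entropy classification on positives, normalized by
the positive count. Two deliberate simplifications:

* **Center-prior assignment** replaces the full optimal-transport assigner:
  a box is routed to the level whose stride satisfies
  `max(w, h) ≤ 8·stride`, and every cell of that level whose center falls
  inside the box is positive (ties go to the smaller box; boxes too small
  to contain a cell center get the nearest cell). This is deterministic
  and testable at desk scale.
* **An always-on auxiliary L1 term** (weight 1) on the raw encoded box
  parameters of positives. The IoU gradient alone is poorly conditioned in
  short from-scratch runs — box outputs drift with the shared features
  while their corrective gradient shrinks with `1/n_pos` — and the L1 term
  provides direct, bounded supervision of offsets and log-sizes. The
  reference YOLOX training enables the same term for its final epochs; at
  desk scale we keep it on throughout.

Cross mini-batch normalization is implemented as standard batch
normalization, and mosaic-style "splicing" augmentation is applied as
offline dataset expansion rather than on the fly.

Gradients are hand-written per layer (im2col convolutions with a fast
pointwise path, depthwise kernels, batch-norm batch statistics, ECA, the
ASFF softmax blend) and are verified against central finite differences in
the test suite at ~1e-8 relative error.

## Channel pruning

Compression follows the batch-norm scaling-factor workflow. Because the BN
output scales with γ, |γ| quantifies channel importance; L1 sparsity
training adds `λ·Σ|γ|` (subgradient `λ·sign γ`, default λ = 0.001, lr
1e-4, batch 16, 100 epochs over the sparsity set) to drive unimportant
scales toward zero. Pruning then:

1. builds **coupled channel groups** with a union-find over channel slots:
   residual additions couple their operands elementwise, depthwise
   convolutions couple input to output 1:1, ASFF blends couple the three
   resized inputs, and Focus copies its input channels. Groups touching the
   stem, the input, or biased output convolutions are never pruned.
2. scores each group by its **largest** member |γ| — the intersection
   rule: a coupled set is removable only when every member is unimportant —
   and removes the cheapest groups until `floor(ratio · n_prunable)`
   channels are gone (default ratio 0.65). For uncoupled layers this
   reduces to the classic global nearest-rank quantile threshold. A
   proportional per-layer floor (`layer_floor`, default 0.2, never below
   one channel) keeps a working reserve in every layer: γ magnitudes are
   only comparable across layers after long sparsity training, and in
   short runs — especially with a backbone whose γ were frozen at their
   initial value — a purely global threshold strangles whole neck layers.
   The ratio is anchored to the *original* network, so re-planning a
   pruned network at the same ratio removes nothing (idempotence).
3. **removes channels function-preservingly.** A removed channel's output
   is the constant `act(β)` when γ = 0. That constant is folded into
   consumers: into the bias of biased 1×1 convolutions; into the running
   mean of the batch norm following unbiased 1×1 convolutions; and, for
   k > 1 kernels, as a cached spatial correction map obtained by convolving
   the constant with the removed kernel slices — zero padding makes the
   naive scalar absorption wrong near map borders (errors around 1e-2),
   while the spatial fold is exact to float precision. Constants that pass
   an ECA gate are folded dynamically with the per-image gate value.
   Constants blended by ASFF's position-dependent weights are folded with
   their mean — the one knowingly approximate case (fine-tuning absorbs
   it). Removing exact-zero-γ channels on convolutional paths changes
   outputs by less than 1e-5 on random inputs; the test suite checks this
   on a CSP-family network where the fold is exact everywhere.

Fine-tuning afterwards uses a linear warm-up over the first 10% of steps,
then cosine decay.

## Evaluation

Matching is greedy per class in descending score order at IoU ≥ 0.5
(configurable): each detection takes the unmatched truth of highest IoU at
or above the threshold, unmatched truths are false negatives. Precision,
recall and F1 use the 0/0 → 0 convention. Average precision integrates the
full precision envelope over recall ("all-point"), since the definition is
a true integral; 11-point interpolation is available as an option. mAP
averages classes with ground truth. Throughput is `FPS = N/T`.

## Synthetic scenes

The generator emulates the study conditions without any downloaded data:
a textured green-foliage background; each larva a curved Bezier capsule —
young: brown, mottled, with a pale saddle patch, drawn at 0.75 scale; old:
green, smooth, with a sheen stripe and small orange horn protrusions; leaf
ellipses drawn over each larva until its measured covered fraction is
within 0.05 of the occlusion target; and front/side/back lighting as
global photometric transforms (backlighting: gain 0.55, offset −10,
desaturation). Ground truth (bounding boxes from the rasterized masks and
per-object occlusion fractions recounted from the final pixel-owner map)
is exact by construction. Defaults: 256-px canvas, 1–3 larvae, even class
mix, occlusion targets uniform on [0, 0.6], lighting modes uniform.

What passing tests on these scenes show: that the full pipeline — data
I/O, assignment, optimization, suppression, pruning, evaluation — is
numerically correct and can learn a localized two-class detection task end
to end. What they do not show: photometric realism, the long-tailed pose
and clutter distribution of real orchards, camera noise, or the accuracy
levels reported on real imagery; none of the mAP values measured on
synthetic scenes transfer to field data.

## Desk-scale problem sizes

The test suite exercises the pipeline at sizes a laptop CPU handles in
minutes, chosen once as the package's smoke configuration: `pest-nano`
(width 0.125, depth 0.11) at 256² on 64 training and 16 held-out scenes;
two-phase training scaled to 10 + 10 epochs at batch 2 (smaller batches
buy more SGD steps at equal cost, which matters far more than batch
statistics at this scale — though not below 2: single-image batch
statistics destabilize BN), with peak rates 3e-3 (frozen phase) and
1.5e-3; sparsity training scaled to 2 epochs; post-prune fine-tuning 30
epochs at peak 2.5e-3 (the pruned network is several times cheaper per
step, so the recovery run affords more epochs than the original
training). Unit tests
use 64-px inputs and width 0.125 throughout. Reference parameter counting
builds the full s/m/x graphs without allocating weights.

## Known limitations

* The engine is a teaching/verification implementation: dense
  double-precision arrays on one CPU core. It is faithful, not fast; no
  GPU, no float32, no SIMD beyond BLAS.
* SimOTA assignment, mixed precision, distributed training, Nano/Tiny
  depthwise variants, COCO-style mAP@[.5:.95] and rotated boxes are out of
  scope.
* Published FLOPs tables for the reference variants do not follow a single
  convention; both conventions are reported and neither is forced to match.
* Pruning exactness is guaranteed for zero-γ channels on convolutional
  paths; attention-gated and ASFF-blended constants are folded dynamically
  or approximately as described above.
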
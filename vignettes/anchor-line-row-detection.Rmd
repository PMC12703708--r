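---
title: "Anchor-line crop-row detection: model, losses and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-line crop-row detection: model, losses and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Visual navigation of field machinery in young maize requires locating the
crop rows in an RGB camera frame. A row is an elongated, nearly straight
structure running from the bottom of the frame toward a vanishing point;
bounding boxes represent it poorly. `croprows` treats each row as a single
regression target: a learnable straight-line prior (an *anchor line*,
parameterized by its bottom end point, direction angle and length) plus a
small horizontal offset at each of N uniformly spaced scanlines. The
package implements the full train/infer/evaluate pipeline: row geometry,
a Row-IoU loss, a dual-axis squeeze-attention ROI module, a cascaded
refinement network on a residual backbone, dynamic positive assignment,
the thickened-mask F1 evaluation protocol, and a deterministic synthetic
field-scene generator that stands in for field data.

## Row representation

A row annotation is an ordered polyline with strictly increasing y.
`sample_row()` discretizes it at the scanlines `y_i = H/(N-1) * i`,
`i = 0..N-1` (0-based, so the last scanline is exactly the image bottom;
it is nudged by 1e-9 px for raster safety). Scanlines outside the
polyline's vertical span are flagged invalid. N is not dictated by the
representation; the package default is 40 scanlines (36 in the tiny
profile), enough that linear interpolation between scanlines is well
below the evaluation stroke width.

An anchor line realizes abscissae through
`x_ref(i) = start_x + (start_y - y_i) / tan(theta)`, with `theta` the
angle to the positive x-axis, strictly inside (0, pi) so the line is
never parallel to a scanline. Anchors are parameterized at their bottom
end and point upward, matching the camera geometry in which rows enter
the frame from the bottom. Length is real-valued during regression (a
smooth-l1 target needs a continuous quantity) and is rounded up only when
gating which scanlines are valid.

## Row-IoU loss

Each sampled point is extended horizontally by a half-length `e` to a
segment `[x - e, x + e]`. The signed segment IoU is
`(2e - d) / (2e + d)` with `d = |x_pred - x_gt|`; the numerator goes
negative for disjoint segments, which keeps gradients informative when a
prediction is far from its row. The row-level RIoU is the **ratio of
summed overlaps to summed unions** over scanlines (not the mean of
per-scanline IoUs), and the loss is `1 - RIoU` in [0, 2]. Summation runs
over the ground truth's valid scanlines regardless of prediction
validity, since predictions are dense along their anchor.

Choices the loss leaves open, fixed here:

* `e = 15` px at network resolution, configurable. With 50-px evaluation
  strokes this makes the loss saturate roughly where the evaluation stops
  giving credit.
* The union denominator carries an `eps = 1e-9` stabilizer; a zero union
  is impossible for `e > 0` but the guard is free.
* The gradient is analytic:
  `d(1 - O/U)/dx_i = sign(x_i - xg_i) (U + O) / U^2`, implemented in
  `riou_loss_grad()` and as a custom autodiff op.

The auxiliary terms are standard: focal classification
(`alpha = 0.25, gamma = 2`), and smooth-l1 (`beta = 1`) on the four
anchor parameters with theta expressed as `theta/pi` so a radian-scale
error stays commensurate with pixel-scale errors. The default term
weights are `w_cls = 2, w_xytl = 0.1, w_riou = 2`: the anchor-parameter
term operates on raw pixel units and would otherwise dominate the shared
trunk's gradients; the realized-row geometry is primarily carried by the
Row-IoU term with the parameter term as a mild prior.

## Dual-axis squeeze attention

The ROI module enriches line-pooled features with global context at cost
`H^2 + W^2` dot products per map instead of `(HW)^2`. Queries come from a
single anchor line; they are projected and bilinearly **scattered** onto a
zero map at the anchor's sample positions, which reconciles the
line-provenance of the query with the spatial reshape the axis squeeze
requires. Keys and values are dense 1x1 projections of the feature map.
Each of the three maps is averaged along one axis (height-squeezed H x C
and width-squeezed W x C forms), softmax attention runs per axis, and the
per-position output is the sum of the two axis readouts.

A convolutional detail-enhancement branch compensates for what the
squeeze discards: the mean line feature is projected and broadcast,
concatenated with dense key/value projections, passed through a 3x3
convolution, channel normalization and ReLU, projected back to C channels
and squashed by a logistic to (0, 1). The gate fuses multiplicatively
with a residual: `out = gate * y + y`. The fusion rule, the logistic
squash and the normalization flavor are package choices; the gated
residual keeps the attention path intact when the gate saturates low.

A full (non-squeezed) attention reference sits behind
`attention_mode = "full"` for the structural ablation; on 1x1 maps the
two coincide exactly. Whether each anchor gets a private query map or all
anchors share one per image is an open design point; the package scatters
all anchor points of an image into one shared map per stage, which keeps
the cost independent of the anchor count.

## Network and cascade

A standard 18-layer residual backbone (width-multiplied for the tiny
profile) feeds a three-level pyramid at strides 8/16/32 with top-down
fusion. Stage 1 pools along the initial anchors p0 on the deepest map;
its head predicts score, parameter deltas and offsets, giving p1 = p0 +
deltas; stage 2 repeats on the middle fusion level along p1; stage 3 on
the finest fused map along p2. All three stages are supervised with equal
weights (the cascade text names the heads but not a weighting). Anchor
*positions* used for pooling are detached between stages - gradients do
not flow through sampling coordinates - which is the standard two-stage
detector treatment and keeps bilinear sampling position-free; the anchor
*parameters* remain in-graph, so refinement consistency
`p_k = p_(k-1) + deltas_k` holds exactly.

Normalization throughout is per-image, per-channel spatial
standardization with a learned affine (instance-style). It is identical
in training and evaluation, works at batch size 1 and keeps forward
passes bit-reproducible; cross-image batch statistics would buy nothing
at these batch sizes.

Head architecture (unspecified upstream): two shared fully connected
layers over the flattened N x C pooled line features, then separate
linear branches for score, deltas (scaled to roughly 10% of the input
dimensions per unit), and per-scanline offsets. 64 anchors by default;
priors spread 70% along the bottom border and 15% along each lower side
border, angles uniform in (15, 165) degrees, trainable.

The focal classification sum is normalized by the number of positives
rather than the number of anchors, the usual dense-detector convention;
normalizing by anchors starves the score head of gradient at 64 anchors
per image.

## Dynamic assignment

The assignment cost is `w_sim * (c_dis * c_xy * c_theta)^2 + w_cls *
focal`, with the three similarity components scaled to [0, 1] by the
image width, the image diagonal and pi respectively (the normalizers are
package choices; the upstream description says only "scaled to [0, 1]").
Per ground truth, `k = clamp(round(sum of top-4 positive Row-IoU
values), 1, 4)` lowest-cost predictions become positive; a prediction
claimed twice goes to the cheaper ground truth, and a ground truth
emptied by conflicts takes its cheapest unassigned prediction. Defaults
`w_sim = 3, w_cls = 1, topk_pool = 4` are declared, not inferred. The
exported `assign()` is validated against an exhaustive enumeration of the
same rule on small instances, and the vectorized trainer path shares the
rule implementation with it.

## Evaluation protocol

Predicted and ground-truth rows are rasterized as 50-px-wide strokes
(square caps, joins filled, no anti-aliasing) at the annotation
resolution; mask IoU is intersection over union of the strokes. The
rasterizer includes a pixel when its center falls inside the stroke
rectangle under a half-open horizontal interval, which makes stroke
widths exact: a full-height vertical line at x = 50 with width 50 on a
100x100 grid covers exactly the column interval [25, 75), 5000 pixels.

Per image the pred x gt IoU matrix is built once and a one-to-one
matching maximizing total IoU is computed (bitmask dynamic programming,
exact); the same matching is reused across thresholds 0.50-0.95.
"Exceeds the threshold" is read strictly (IoU > tau). F1 per threshold
and their mean (mF1, reported on the 0-100 scale) follow. Matching
optimally rather than greedily, and thickening at annotation resolution,
are pinned package decisions where the protocol description is silent.

## Synthetic scenes

The generator emulates the capture conditions the detector is meant for:
parallel world rows on flat ground projected through a pinhole camera
pitched 30-60 degrees below the horizon (45 by default), yielding
converging straight image rows with exact post-projection centerlines as
ground truth. Green leaf-blob clusters are placed along each centerline
at fixed world spacing with jitter and seedling gaps (10% by default);
weeds are isotropic clutter at 0.08 blobs per kilopixel; illumination
gain in [0.7, 1.3], optional motion blur, and wind-lodging jitter that
displaces plant blobs laterally about the centerline without moving the
centerline itself. Photometric perturbations never touch the annotations.
Scenes default to 1280x720; the test and acceptance suites generate at
640x360, the same geometry at half scale, to keep mask rasterization
cheap.

What passing tests on these scenes shows: the pipeline can recover known
row geometry end-to-end from images whose cues (green-on-soil contrast,
row convergence, clutter) resemble field data. What it does not show:
robustness to real canopy texture, growth-stage variation, or domain
shift - the generator renders blobs, not plants.

## Training configuration and problem sizes

The full profile mirrors the reference setup: input 3x800x320, AdamW at
1e-4, polynomial decay with power 0.9 (the upstream description of a
"cosine schedule (power factor 0.9)" is internally inconsistent; poly-0.9
is the default and cosine is available via `schedule = "cosine"`),
70 epochs, batch 40. The tiny profile - the one the package's tests and
acceptance checks exercise on one CPU - uses input 3x320x160, 64 anchors,
N = 36, width multiplier 1/8, a 3x3 stem convolution, 30 epochs, batch 8
and AdamW at 2e-3; small networks on short schedules tolerate and need
a larger rate than the full profile's 1e-4. Augmentation is seeded horizontal flip (annotations
flipped too) and photometric jitter. Everything - initialization, data
order, augmentation - derives from one master seed, so loss curves
reproduce exactly.

The test suite trains scaled-down instances (tens of scenes, 10-20
epochs, one seed) chosen so the whole suite completes in well under half
an hour; the acceptance script trains a mid-sized instance (about a
hundred scenes) and states the size it used alongside each reported
number. The smooth-l1 ablation arm replaces the Row-IoU term with
smooth-l1 on the realized abscissae, weighted by `w_riou / e` so the two
arms see comparable gradient magnitudes at large errors.

## Known limitations

* The backbone and heads are sized for CPU-scale experiments; absolute
  parameter counts and throughput are not comparable to GPU
  implementations and are explicitly out of scope.
* The generator's rows are straight; curved rows would require spline
  anchors, a stated non-goal of the representation.
* Instance-style normalization means activations depend on per-image
  statistics; severely out-of-distribution illumination shifts both
  features and normalization, which the photometric augmentation only
  partly covers.
* The mask rasterizer is exact for the stroke convention stated above;
  renderers with different cap/rounding conventions will disagree by
  border pixels.
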
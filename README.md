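# croprows

Anchor-line crop-row detection for field images, in R.

Machine vision for field machinery needs the maize rows in a camera frame,
not boxes around individual plants. `croprows` detects each row as a single
elongated target: a learnable straight-line prior — an **anchor line** with
bottom start point `(x, y)`, direction angle `θ ∈ (0, π)` and length `l` —
refined by a cascaded convolutional network that regresses a horizontal
offset at each of `N` uniformly spaced scanlines `y_i = H/(N−1)·i`. The
package is for researchers in agricultural image analysis who want a fully
inspectable, CPU-reproducible implementation of this row-as-line paradigm:
every component, from the loss geometry to the network cascade, is plain R
backed by BLAS.

The core pieces:

* **Row-IoU loss.** Each sampled point is widened by a half-length `e` to a
  segment; the signed segment IoU is `(2e − d)/(2e + d)` with
  `d = |x_pred − x_gt|` (negative when disjoint), and the row-level RIoU is
  the ratio of summed overlaps to summed unions across scanlines. The
  training loss is `L = 1 − RIoU ∈ [0, 2]`, with analytic gradients.
* **Dual-axis squeeze attention.** Query/key/value maps are averaged along
  one spatial axis each, so attention matrices are `H×H` and `W×W` instead
  of `(HW)×(HW)`; a convolutional detail-enhancement gate recovers local
  structure, fused as `gate ⊙ y + y`.
* **Cascade.** A residual backbone with feature-pyramid fusion; anchors
  `p0 → p1 → p2` are refined by three heads operating on features pooled
  along each anchor line.
* **Dynamic assignment.** Per ground-truth row, `k` lowest-cost predictions
  become positives, `k = clamp(round(Σ top-4 positive RIoU), 1, 4)`, with
  cost `ω_sim·(c_dis·c_xy·c_θ)² + ω_cls·focal`.
* **Evaluation.** Rows are thickened to 50-px masks; F1 is computed at mask
  IoU thresholds 0.50–0.95 and averaged into **mF1** (0–100).
* **Synthetic scenes.** A deterministic generator renders perspective-
  projected maize rows (pinhole camera at 30–60° pitch, plant blobs, weeds,
  seedling gaps, illumination/blur/lodging perturbations) with exact
  polyline ground truth, plus LabelMe-dialect JSON I/O — so the whole
  train/infer/evaluate loop runs without field data.

## Worked example

Generate a synthetic field dataset, fit the tiny (CPU-scale) profile, and
evaluate:

```r
library(croprows)

cfg <- scene_config(image_width = 640, image_height = 360, seed = 100)
train <- generate_dataset(cfg, 200, "train", "scenes")
cfg$seed <- 900
val <- generate_dataset(cfg, 50, "val", "scenes")

fit <- row_detector(train, val, profile = "tiny",
                    tcfg = train_config("tiny", epochs = 30, val_every = 5),
                    seed = 1)
print(fit)
```

```
Anchor-line crop-row detector
  profile: tiny  input 320x160  anchors 64  N 36  params 506,819
  attention: dae  fpn: TRUE  regression: riou
  trained 30 epochs, final loss 0.7313, best val mF1 92.19
```

The history records the loss breakdown and periodic validation; at epoch 30
this run reports **mF1 92.2** and **F1@50 98.4** on the 50 held-out scenes:
of the ~245 ground-truth rows, nearly all are detected within half a stroke
width, and the mean over the stricter thresholds (0.55…0.95) stays high
because the regressed scanline offsets land within a few pixels of the
projected centerlines. Detections on a new image:

```r
pr <- predict(fit, val$image[1])
length(pr[[1]]$predictions)   # rows found after NMS, e.g. 5
pr[[1]]$scores                # detection confidences
plot(fit, val$image[1])       # overlay of the detected centerlines
```

`infer()` writes predictions back out as LabelMe linestrip JSON so that
`evaluate_cmd(pred_dir, gt_dir, ...)` — or any external tool speaking the
same dialect — can score them. A thin CLI over these functions lives in
`inst/cli/croprows.R` (subcommands `synth`, `train`, `infer`, `eval`,
`ablate`).

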
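Package: croprows
Title: Anchor-Line Crop-Row Detection with Row-IoU Training and Mask-F1 Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects maize crop rows in field images by regressing each row as a
    single elongated target from a learnable straight-line (anchor-line) prior.
    Implements the row geometry (uniformly sampled row polylines, anchor
    parameterizations), a differentiable Row-IoU loss over horizontally extended
    per-row segments, a dual-axis squeeze attention ROI module with a
    convolutional detail-enhancement gate, a cascaded anchor-refinement network
    on a residual backbone with feature-pyramid fusion, dynamic positive-sample
    assignment, and the thickened-mask F1 evaluation protocol (F1 at mask-IoU
    thresholds 0.50-0.95 and their mean). Includes a deterministic synthetic
    field-scene generator with exact polyline ground truth and LabelMe-dialect
    annotation input/output, so the full train/infer/evaluate pipeline runs
    end-to-end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
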
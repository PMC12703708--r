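# Row-IoU: per-scanline segment IoU of horizontally extended points, its
# row-level aggregation (a ratio of summed overlaps to summed unions), the
# 1 - RIoU loss, and the auxiliary focal / smooth-l1 losses of the training
# objective.

#' Row-IoU configuration
#'
#' @param extension_e half-length e (px) by which each sampled point is
#'   extended horizontally before computing segment overlap.
#' @param eps small positive stabilizer added to the union denominator.
#' @return an object of class `riou_config`.
#' @export
riou_config <- function(extension_e = 15, eps = 1e-9) {
  stopifnot(extension_e > 0, eps > 0)
  structure(list(extension_e = extension_e, eps = eps), class = "riou_config")
}

#' Loss weights of the composite training objective
#'
#' total = w_cls * cls + w_xytl * xytl + w_riou * riou, where cls is focal
#' classification, xytl is smooth-l1 on (start_x, start_y, theta, length),
#' and riou is the 1 - RIoU regression loss on the realized row.
#'
#' @param w_cls,w_xytl,w_riou nonnegative term weights.
#' @param focal_alpha,focal_gamma focal-loss parameters.
#' @param smooth_l1_beta smooth-l1 transition point (px).
#' @return an object of class `loss_weights`.
#' @export
loss_weights <- function(w_cls = 2, w_xytl = 0.1, w_riou = 2,
                         focal_alpha = 0.25, focal_gamma = 2,
                         smooth_l1_beta = 1) {
  w <- c(w_cls, w_xytl, w_riou, focal_alpha, focal_gamma, smooth_l1_beta)
  stopifnot(all(is.finite(w)), all(w >= 0))
  structure(list(w_cls = w_cls, w_xytl = w_xytl, w_riou = w_riou,
                 focal_alpha = focal_alpha, focal_gamma = focal_gamma,
                 smooth_l1_beta = smooth_l1_beta), class = "loss_weights")
}

#' IoU of two horizontally extended point segments
#'
#' Both points are extended to segments [x - e, x + e]; the signed IoU is
#' overlap / union, which reduces to (2e - d) / (2e + d) with d = |xp - xg|.
#' The overlap (numerator) goes negative when the segments are disjoint,
#' which keeps the quantity informative for far-apart rows.
#'
#' @param xp,xg predicted and ground-truth x positions (px); vectorized.
#' @param cfg a [riou_config()].
#' @return signed IoU values in (-1, 1].
#' @export
segment_iou <- function(xp, xg, cfg = riou_config()) {
  e <- cfg$extension_e
  num <- pmin(xp + e, xg + e) - pmax(xp - e, xg - e)
  den <- pmax(xp + e, xg + e) - pmin(xp - e, xg - e)
  num / (den + cfg$eps)
}

#' Row-level IoU between a predicted and a ground-truth sampled row
#'
#' Ratio of summed per-scanline overlaps to summed unions (not the mean of
#' per-scanline IoUs), accumulated over the scanlines where the ground
#' truth is valid. Predictions are dense along the anchor, so prediction
#' validity is not consulted.
#'
#' @param pred,gt [sampled_row()] objects with equal `n_points`.
#' @param cfg a [riou_config()].
#' @return scalar in [-1, 1]; 1 iff xs agree exactly at every summed scanline.
#' @export
row_iou <- function(pred, gt, cfg = riou_config()) {
  stopifnot(inherits(pred, "sampled_row"), inherits(gt, "sampled_row"))
  if (pred$n_points != gt$n_points)
    cr_stop("pred and gt must share n_points", "croprows_invalid_input")
  m <- gt$valid
  if (!any(m)) cr_stop("ground-truth row has no valid samples", "croprows_invalid_target")
  e <- cfg$extension_e
  d <- abs(pred$xs[m] - gt$xs[m])
  sum(2 * e - d) / (sum(2 * e + d) + cfg$eps)
}

#' Row-IoU loss (1 - RIoU)
#'
#' @inheritParams row_iou
#' @return scalar loss in [0, 2]; zero exactly at the ground truth.
#' @export
riou_loss <- function(pred, gt, cfg = riou_config()) 1 - row_iou(pred, gt, cfg)

#' Analytic gradient of the Row-IoU loss in the predicted abscissae
#'
#' d(1 - O/U)/dx_i = sign(x_i - xg_i) * (U + O) / U^2 at ground-truth-valid
#' scanlines and 0 elsewhere, with O and U the summed overlaps and unions.
#' Used for direct gradient-based recovery experiments and by the trainer.
#'
#' @param pred_xs,gt_xs numeric vectors of abscissae (px).
#' @param gt_valid logical vector masking the summed scanlines.
#' @param cfg a [riou_config()].
#' @return gradient vector of the same length.
#' @export
riou_loss_grad <- function(pred_xs, gt_xs, gt_valid, cfg = riou_config()) {
  e <- cfg$extension_e
  g <- numeric(length(pred_xs))
  d <- abs(pred_xs[gt_valid] - gt_xs[gt_valid])
  O <- sum(2 * e - d)
  U <- sum(2 * e + d) + cfg$eps
  s <- sign(pred_xs[gt_valid] - gt_xs[gt_valid])
  g[gt_valid] <- s * (U + O) / U^2
  g
}

# Elementwise smooth-l1 (Huber) value; beta is the quadratic-linear knee.
smooth_l1 <- function(d, beta) {
  a <- abs(d)
  ifelse(a < beta, 0.5 * d^2 / beta, a - 0.5 * beta)
}

#' Smooth-l1 regression loss on anchor parameters
#'
#' Mean smooth-l1 over the four anchor components (start_x, start_y,
#' theta, length), with theta expressed in normalized units (theta / pi)
#' so a radian-scale error stays commensurate with pixel-scale errors.
#'
#' @param pred,gt [anchor_line()] objects.
#' @param beta smooth-l1 transition point.
#' @return scalar loss, zero exactly when the anchors coincide.
#' @export
smooth_l1_xytl <- function(pred, gt, beta = 1) {
  d <- c(pred$start_x - gt$start_x,
         pred$start_y - gt$start_y,
         (pred$theta - gt$theta) / pi,
         pred$length - gt$length)
  mean(smooth_l1(d, beta))
}

#' Focal classification loss
#'
#' Positives: -alpha (1-p)^gamma log p; negatives: -(1-alpha) p^gamma
#' log(1-p). Scores exactly at 0 or 1 are clamped.
#'
#' @param score predicted probabilities; vectorized.
#' @param is_positive logical vector of the same length.
#' @param alpha,gamma focal parameters.
#' @return vector of per-sample losses.
#' @export
focal_loss <- function(score, is_positive, alpha = 0.25, gamma = 2) {
  p <- clamp(score, 1e-7, 1 - 1e-7)
  ifelse(is_positive,
         -alpha * (1 - p)^gamma * log(p),
         -(1 - alpha) * p^gamma * log(1 - p))
}
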
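# Dynamic positive-sample assignment: each ground-truth row receives a
# dynamically chosen number k of lowest-cost predictions as positives,
# where the cost blends a geometric similarity term with the focal
# classification cost, and k is the clamped rounded sum of the top
# Row-IoU candidates.

#' Assignment parameters
#'
#' @param w_sim,w_cls nonnegative weights of the similarity and
#'   classification cost terms.
#' @param topk_pool number of candidates pooled when choosing dynamic k.
#' @param norm_width image width (px), normalizes the mean point distance.
#' @param norm_diag image diagonal (px), normalizes the start-point distance.
#' @return an object of class `assignment_params`.
#' @export
assignment_params <- function(w_sim = 3, w_cls = 1, topk_pool = 4,
                              norm_width = 800, norm_diag = sqrt(800^2 + 320^2)) {
  stopifnot(w_sim >= 0, w_cls >= 0, topk_pool >= 1)
  structure(list(w_sim = w_sim, w_cls = w_cls, topk_pool = topk_pool,
                 norm_width = norm_width, norm_diag = norm_diag),
            class = "assignment_params")
}

#' Geometric similarity cost between a prediction and a ground-truth row
#'
#' c_dis is the mean pixel distance over the ground truth's valid sample
#' points (scaled by the image width), c_xy the start-point distance
#' (scaled by the diagonal), c_theta the angle difference over pi; each is
#' clamped to [0, 1] and the combined similarity cost is their squared
#' product.
#'
#' @param pred a [row_prediction()].
#' @param gt_row [sampled_row()] ground truth.
#' @param gt_anchor [anchor_line()] parameters of the ground-truth row.
#' @param params an [assignment_params()].
#' @return named list (c_dis, c_xy, c_theta, c_sim).
#' @export
similarity_cost <- function(pred, gt_row, gt_anchor, params) {
  pr <- anchor_to_points(pred$anchor, pred$offsets, gt_row$n_points, gt_row$height)
  m <- gt_row$valid
  if (!any(m)) return(list(c_dis = 1, c_xy = 1, c_theta = 1, c_sim = 1))
  c_dis <- clamp(mean(abs(pr$xs[m] - gt_row$xs[m])) / params$norm_width, 0, 1)
  c_xy <- clamp(sqrt((pred$anchor$start_x - gt_anchor$start_x)^2 +
                       (pred$anchor$start_y - gt_anchor$start_y)^2) / params$norm_diag,
                0, 1)
  c_theta <- clamp(abs(pred$anchor$theta - gt_anchor$theta) / pi, 0, 1)
  list(c_dis = c_dis, c_xy = c_xy, c_theta = c_theta,
       c_sim = (c_dis * c_xy * c_theta)^2)
}

# full cost matrices between prediction and ground-truth lists
assignment_costs <- function(preds, gts, params, cfg,
                             focal_alpha = 0.25, focal_gamma = 2) {
  np <- length(preds); ng <- length(gts)
  c_sim <- c_cls <- riou <- matrix(0, np, ng)
  for (i in seq_len(np)) {
    pr <- anchor_to_points(preds[[i]]$anchor, preds[[i]]$offsets,
                           gts[[1]]$row$n_points, gts[[1]]$row$height)
    for (j in seq_len(ng)) {
      sc <- similarity_cost(preds[[i]], gts[[j]]$row, gts[[j]]$anchor, params)
      c_sim[i, j] <- sc$c_sim
      c_cls[i, j] <- focal_loss(preds[[i]]$score, TRUE, focal_alpha, focal_gamma)
      riou[i, j] <- row_iou(pr, gts[[j]]$row, cfg)
    }
  }
  list(c_sim = c_sim, c_cls = c_cls, riou = riou,
       c_assign = params$w_sim * c_sim + params$w_cls * c_cls)
}

# dynamic k per ground truth: clamped rounded sum of the positive part of
# the top-`topk_pool` Row-IoU candidates
dynamic_k <- function(riou_col, topk_pool) {
  v <- sort(riou_col, decreasing = TRUE)
  v <- v[seq_len(min(topk_pool, length(v)))]
  max(1L, min(topk_pool, as.integer(round(sum(pmax(v, 0))))))
}

# the assignment rule on precomputed matrices: per gt take its dynamic-k
# lowest-cost preds; conflicts go to the cheaper gt (ties to the lower
# index); gts emptied by conflicts take their cheapest unassigned pred
assign_rule <- function(c_assign, riou_mat, topk_pool) {
  np <- nrow(c_assign); ng <- ncol(c_assign)
  claimed <- matrix(FALSE, np, ng)
  for (j in seq_len(ng)) {
    k <- dynamic_k(riou_mat[, j], topk_pool)
    ord <- order(c_assign[, j])
    claimed[ord[seq_len(min(k, np))], j] <- TRUE
  }
  pred_to_gt <- rep(NA_integer_, np)
  for (i in seq_len(np)) {
    js <- which(claimed[i, ])
    if (length(js) == 0) next
    pred_to_gt[i] <- js[which.min(c_assign[i, js])]
  }
  for (j in seq_len(ng)) {
    if (any(pred_to_gt == j, na.rm = TRUE)) next
    free <- which(is.na(pred_to_gt))
    if (length(free) == 0) next
    pred_to_gt[free[which.min(c_assign[free, j])]] <- j
  }
  pred_to_gt
}

#' Assign predictions to ground-truth rows as positive samples
#'
#' Per ground truth, the k lowest-cost predictions become positives with
#' k = clamp(round(sum of top-`topk_pool` positive Row-IoU values), 1,
#' topk_pool). A prediction claimed by several ground truths goes to the
#' one with lower cost (ties to the lower index); a ground truth left with
#' no positive afterwards takes its lowest-cost still-unassigned
#' prediction, so every ground truth keeps at least one positive whenever
#' enough predictions exist. All remaining predictions are negatives.
#'
#' @param preds list of [row_prediction()] objects (nonempty).
#' @param gts list of ground truths, each a list with elements `row`
#'   ([sampled_row()]) and `anchor` ([anchor_line()]).
#' @param params an [assignment_params()].
#' @param cfg a [riou_config()].
#' @return an object of class `assignment`: list with `pos_pairs`
#'   (2-column matrix pred/gt index) and `pred_to_gt` (integer vector,
#'   NA for negatives).
#' @export
assign <- function(preds, gts, params = assignment_params(), cfg = riou_config()) {
  np <- length(preds)
  if (np == 0) cr_stop("no predictions to assign", "croprows_invalid_input")
  if (length(gts) == 0)
    return(structure(list(pos_pairs = cbind(integer(0), integer(0)),
                          pred_to_gt = rep(NA_integer_, np)),
                     class = "assignment"))
  cm <- assignment_costs(preds, gts, params, cfg)
  pred_to_gt <- assign_rule(cm$c_assign, cm$riou, params$topk_pool)
  pos <- which(!is.na(pred_to_gt))
  structure(list(pos_pairs = cbind(pred = pos, gt = pred_to_gt[pos]),
                 pred_to_gt = pred_to_gt),
            class = "assignment")
}

#' Composite training loss over one or more supervised stages
#'
#' Classification (focal) runs over all predictions against their
#' positive/negative labels; the smooth-l1 anchor-parameter term and the
#' Row-IoU term average over positives only. Stages are weighted equally.
#'
#' @param outputs list of stage outputs; each a list with `preds` (list of
#'   [row_prediction()]) and `assignment` (an `assignment` for that stage).
#' @param gts ground-truth list as in [assign()].
#' @param weights a [loss_weights()].
#' @param cfg a [riou_config()].
#' @return an object of class `loss_breakdown`: cls, xytl, riou, total.
#' @export
total_loss <- function(outputs, gts, weights = loss_weights(), cfg = riou_config()) {
  cls_sum <- xytl_sum <- riou_sum <- 0
  for (st in outputs) {
    preds <- st$preds; asg <- st$assignment
    scores <- vapply(preds, function(p) p$score, 0)
    is_pos <- !is.na(asg$pred_to_gt)
    cls_sum <- cls_sum + mean(focal_loss(scores, is_pos,
                                         weights$focal_alpha, weights$focal_gamma))
    if (any(is_pos)) {
      xytl_terms <- riou_terms <- numeric(0)
      for (r in seq_len(nrow(asg$pos_pairs))) {
        i <- asg$pos_pairs[r, 1]; j <- asg$pos_pairs[r, 2]
        gt <- gts[[j]]
        xytl_terms <- c(xytl_terms,
                        smooth_l1_xytl(preds[[i]]$anchor, gt$anchor,
                                       weights$smooth_l1_beta))
        pr <- anchor_to_points(preds[[i]]$anchor, preds[[i]]$offsets,
                               gt$row$n_points, gt$row$height)
        riou_terms <- c(riou_terms, riou_loss(pr, gt$row, cfg))
      }
      xytl_sum <- xytl_sum + mean(xytl_terms)
      riou_sum <- riou_sum + mean(riou_terms)
    }
  }
  total <- weights$w_cls * cls_sum + weights$w_xytl * xytl_sum +
    weights$w_riou * riou_sum
  structure(list(cls = cls_sum, xytl = xytl_sum, riou = riou_sum, total = total),
            class = "loss_breakdown")
}
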
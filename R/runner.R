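# Training, inference and evaluation orchestration. The fitting function
# row_detector() trains the cascaded anchor-line network on a manifest of
# images + LabelMe polyline annotations and returns a classed model object
# with predict / print / summary / plot methods.

#' Training configuration
#'
#' The full profile mirrors the reference training setup (3x800x320 input,
#' AdamW at 1e-4 with polynomial decay power 0.9, 70 epochs, batch 40);
#' the tiny profile is a CPU-scale variant (3x320x160, 64 anchors, N = 36,
#' width multiplier 1/8, 30 epochs, batch 8, AdamW at 2e-3).
#'
#' @param profile "full" or "tiny".
#' @param epochs,batch_size,lr optional overrides.
#' @param schedule "poly" (power 0.9) or "cosine".
#' @param loss_regression "riou" or "smooth_l1" (ablation arm); the
#'   smooth-l1 arm weight is w_riou / extension_e so gradient magnitudes
#'   match the Row-IoU term at large errors.
#' @param weights a [loss_weights()].
#' @param riou a [riou_config()].
#' @param assign_params an [assignment_params()] (normalizers default to
#'   the network input resolution).
#' @param augment enable seeded horizontal-flip + photometric jitter.
#' @param val_every validate (mF1 on the val split) every this many epochs.
#' @param seed master seed for init, data order and augmentation.
#' @return an object of class `train_config`.
#' @export
train_config <- function(profile = c("tiny", "full"), epochs = NULL,
                         batch_size = NULL, lr = NULL,
                         schedule = c("poly", "cosine"),
                         loss_regression = c("riou", "smooth_l1"),
                         weights = loss_weights(), riou = riou_config(),
                         assign_params = NULL, augment = TRUE,
                         val_every = 10, seed = 1L) {
  profile <- match.arg(profile)
  if (profile == "full") {
    if (is.null(epochs)) epochs <- 70
    if (is.null(batch_size)) batch_size <- 40
    if (is.null(lr)) lr <- 1e-4
  } else {
    if (is.null(epochs)) epochs <- 30
    if (is.null(batch_size)) batch_size <- 8
    if (is.null(lr)) lr <- 2e-3
  }
  structure(list(profile = profile, epochs = epochs, batch_size = batch_size,
                 lr = lr, schedule = match.arg(schedule),
                 loss_regression = match.arg(loss_regression),
                 weights = weights, riou = riou, assign_params = assign_params,
                 augment = augment, val_every = val_every,
                 seed = as.integer(seed)),
            class = "train_config")
}

profile_model_config <- function(profile, attention_mode = "dae",
                                 fpn_enabled = TRUE) {
  if (profile == "full")
    model_config(800, 320, num_anchors = 64, n_points = 40, width_mult = 1,
                 attention_mode = attention_mode, fpn_enabled = fpn_enabled)
  else
    model_config(320, 160, num_anchors = 64, n_points = 36, width_mult = 0.125,
                 attention_mode = attention_mode, fpn_enabled = fpn_enabled,
                 stem_kernel = 3L)
}

# ground-truth anchor parameters from a sampled row (least-squares slope)
gt_anchor_from_row <- function(srow) {
  v <- which(srow$valid)
  ys <- sample_ys(srow$n_points, srow$height)
  yv <- ys[v]; xv <- srow$xs[v]
  slope <- if (length(v) > 1 && stats::var(yv) > 0)
    stats::cov(yv, xv) / stats::var(yv) else 0
  theta <- atan2(1, -slope)
  if (theta <= 0 || theta >= pi) theta <- pi / 2
  anchor_line(xv[length(v)], yv[length(v)], clamp(theta, 0.061, pi - 0.061),
              length(v))
}

# load one manifest into memory at the network resolution
load_split <- function(manifest, mcfg) {
  n <- nrow(manifest)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    img <- png::readPNG(manifest$image[i])
    if (length(dim(img)) == 3 && dim(img)[3] > 3) img <- img[, , 1:3]
    ann_w <- dim(img)[2]; ann_h <- dim(img)[1]
    x <- bilinear_resize(img, mcfg$input_width, mcfg$input_height)
    polys <- read_labelme(manifest$annotation[i])
    gts <- lapply(polys, function(p) {
      pts <- p$points
      pts[, 1] <- pts[, 1] * mcfg$input_width / ann_w
      pts[, 2] <- pts[, 2] * mcfg$input_height / ann_h
      pts[, 1] <- clamp(pts[, 1], 0, mcfg$input_width)
      pts[, 2] <- clamp(pts[, 2], 0, mcfg$input_height)
      sr <- sample_row(row_polyline(pts, mcfg$input_width, mcfg$input_height,
                                    p$label),
                       mcfg$n_points, mcfg$input_height)
      list(row = sr, anchor = gt_anchor_from_row(sr))
    })
    gts <- Filter(function(g) sum(g$row$valid) >= 2, gts)
    out[[i]] <- list(image = x, gts = gts, ann_w = ann_w, ann_h = ann_h,
                     annotation = manifest$annotation[i],
                     path = manifest$image[i])
  }
  out
}

# horizontal flip of one loaded sample
flip_sample <- function(smp, mcfg) {
  W <- mcfg$input_width
  smp$image <- smp$image[, dim(smp$image)[2]:1, , drop = FALSE]
  smp$gts <- lapply(smp$gts, function(g) {
    xs <- W - g$row$xs
    sr <- sampled_row(ifelse(g$row$valid, xs, 0), g$row$valid, g$row$height)
    list(row = sr, anchor = gt_anchor_from_row(sr))
  })
  smp
}

# vectorized assignment for the trainer: same rule as assign(), matrices
# built with matrix arithmetic
assign_fast <- function(scores, anchors, xs_mat, gts, params, cfg, weights) {
  A <- length(scores); ng <- length(gts)
  c_sim <- c_cls <- riou_m <- matrix(0, A, ng)
  e <- cfg$extension_e
  cls_cost <- focal_loss(scores, TRUE, weights$focal_alpha, weights$focal_gamma)
  for (j in seq_len(ng)) {
    g <- gts[[j]]
    m <- g$row$valid
    dmat <- abs(xs_mat[, m, drop = FALSE] -
                  matrix(g$row$xs[m], A, sum(m), byrow = TRUE))
    c_dis <- clamp(rowMeans(dmat) / params$norm_width, 0, 1)
    c_xy <- clamp(sqrt((anchors[, 1] - g$anchor$start_x)^2 +
                         (anchors[, 2] - g$anchor$start_y)^2) / params$norm_diag, 0, 1)
    c_th <- clamp(abs(anchors[, 3] - g$anchor$theta) / pi, 0, 1)
    c_sim[, j] <- (c_dis * c_xy * c_th)^2
    c_cls[, j] <- cls_cost
    riou_m[, j] <- rowSums(2 * e - dmat) / (rowSums(2 * e + dmat) + cfg$eps)
  }
  assign_rule(params$w_sim * c_sim + params$w_cls * c_cls, riou_m,
              params$topk_pool)
}

# build the loss nodes for one stage over a batch; returns nodes + stats
stage_loss <- function(tp, net, st, batch_gts, tcfg, aparams, ys) {
  cfg <- net$cfg; A <- cfg$num_anchors; N <- cfg$n_points
  B <- length(batch_gts)
  w <- tcfg$weights; rcfg <- tcfg$riou
  # numeric side: realized anchors/offsets and assignment per image
  anch_val <- st$anchors_pred$val
  offs_val <- st$offsets$val
  score_val <- 1 / (1 + exp(-st$score$val[, 1]))
  pos_mask <- matrix(FALSE, B * A, 1)
  pos_rows <- integer(0); pos_gt <- list()
  for (b in seq_len(B)) {
    gts <- batch_gts[[b]]
    if (length(gts) == 0) next
    rows <- (b - 1) * A + seq_len(A)
    anc <- anch_val[rows, , drop = FALSE]
    anc[, 3] <- clamp(anc[, 3], 0.06, pi - 0.06)
    xs <- anchor_ref_xs(anc, ys) + offs_val[rows, , drop = FALSE]
    p2g <- assign_fast(score_val[rows], anc, xs, gts, aparams, rcfg, w)
    pos <- which(!is.na(p2g))
    pos_mask[rows[pos], 1] <- TRUE
    for (p in pos) {
      pos_rows <- c(pos_rows, rows[p])
      pos_gt[[length(pos_gt) + 1]] <- gts[[p2g[p]]]
    }
  }
  # focal sum normalized by the positive count (not the anchor count), so
  # positive gradients do not vanish among the many negatives
  P <- length(pos_rows)
  cls <- op_scale(tp, op_sum_all(tp, op_focal_logits(tp, st$score, pos_mask,
                                                     w$focal_alpha, w$focal_gamma)),
                  1 / max(1, P))
  if (P == 0)
    return(list(cls = cls, xytl = NULL, reg = NULL, n_pos = 0))
  anch_pos <- op_rows_select(tp, st$anchors_pred, pos_rows)
  offs_pos <- op_rows_select(tp, st$offsets, pos_rows)
  gt4 <- do.call(rbind, lapply(pos_gt, function(g)
    c(g$anchor$start_x, g$anchor$start_y, g$anchor$theta, g$anchor$length)))
  sc4 <- matrix(c(1, 1, 1 / pi, 1), P, 4, byrow = TRUE)
  xytl <- op_mean_all(tp, op_smooth_l1(tp,
    op_sub(tp, op_mul(tp, anch_pos, sc4), gt4 * sc4), w$smooth_l1_beta))
  # realized abscissae as tape nodes
  th <- op_clamp(tp, op_cols_select(tp, anch_pos, 3), 0.06, pi - 0.06)
  xs_node <- op_add(tp,
    op_add(tp, op_bcast_col(tp, op_cols_select(tp, anch_pos, 1), N),
           op_mul(tp, op_sub(tp, op_bcast_col(tp, op_cols_select(tp, anch_pos, 2), N),
                             matrix(ys, P, N, byrow = TRUE)),
                  op_bcast_col(tp, op_cot(tp, th), N))),
    offs_pos)
  gt_xs <- do.call(rbind, lapply(pos_gt, function(g) g$row$xs))
  gt_vd <- do.call(rbind, lapply(pos_gt, function(g) as.numeric(g$row$valid)))
  reg <- if (tcfg$loss_regression == "riou") {
    op_mean_all(tp, op_riou_rows(tp, xs_node, gt_xs, gt_vd, rcfg$extension_e,
                                 rcfg$eps))
  } else {
    diff <- op_mul(tp, op_sub(tp, xs_node, gt_xs), gt_vd)
    op_scale(tp, op_sum_all(tp, op_smooth_l1(tp, diff, w$smooth_l1_beta)),
             1 / max(1, sum(gt_vd)))
  }
  list(cls = cls, xytl = xytl, reg = reg, n_pos = P)
}

# one optimization step over a batch; returns the loss breakdown
train_step <- function(net, batch, tcfg, aparams, params, lr, step_t) {
  cfg <- net$cfg
  B <- length(batch)
  x <- do.call(rbind, lapply(batch, function(s) fm_from_array(s$image)))
  tp <- tape_new()
  fw <- net_forward(net, tp, x, B)
  w <- tcfg$weights
  w_reg <- if (tcfg$loss_regression == "riou") w$w_riou
           else w$w_riou / tcfg$riou$extension_e
  terms <- list(); brk <- c(cls = 0, xytl = 0, riou = 0)
  for (s in 1:3) {
    sl <- stage_loss(tp, net, fw$stages[[s]], lapply(batch, `[[`, "gts"),
                     tcfg, aparams, fw$ys)
    terms[[length(terms) + 1]] <- op_scale(tp, sl$cls, w$w_cls)
    brk["cls"] <- brk["cls"] + sl$cls$val[1]
    if (!is.null(sl$xytl)) {
      terms[[length(terms) + 1]] <- op_scale(tp, sl$xytl, w$w_xytl)
      terms[[length(terms) + 1]] <- op_scale(tp, sl$reg, w_reg)
      brk["xytl"] <- brk["xytl"] + sl$xytl$val[1]
      brk["riou"] <- brk["riou"] + sl$reg$val[1]
    }
  }
  total <- terms[[1]]
  for (k in seq_along(terms)[-1]) total <- op_add(tp, total, terms[[k]])
  if (!is.finite(total$val[1]))
    cr_stop(sprintf("non-finite loss (cls %.3g, xytl %.3g, reg %.3g)",
                    brk["cls"], brk["xytl"], brk["riou"]),
            "croprows_nan_loss")
  backward(tp, total)
  adamw_step(params, lr, t = step_t)
  c(total = total$val[1], brk)
}

# run the network over samples and return post-NMS predictions per image,
# as sampled rows at the annotation resolution
predict_samples <- function(net, samples, score_threshold = 0.4,
                            nms_iou = 0.5, rcfg = riou_config(),
                            batch_size = 8) {
  cfg <- net$cfg
  out <- vector("list", length(samples))
  idx <- seq_along(samples)
  for (chunk in split(idx, ceiling(idx / batch_size))) {
    x <- do.call(rbind, lapply(samples[chunk], function(s) fm_from_array(s$image)))
    tp <- tape_new()
    fw <- net_forward(net, tp, x, length(chunk))
    for (k in seq_along(chunk)) {
      preds <- realize_predictions(net, fw, k)
      kept <- row_nms(preds, iou_threshold = nms_iou,
                      score_threshold = score_threshold, cfg = rcfg,
                      n_points = cfg$n_points, height = cfg$input_height)
      s <- samples[[chunk[k]]]
      rows_eval <- lapply(kept, function(p) {
        sr <- anchor_to_points(p$anchor, p$offsets, cfg$n_points,
                               cfg$input_height)
        rescale_row(sr, cfg$input_width, cfg$input_height, s$ann_w, s$ann_h)
      })
      out[[chunk[k]]] <- list(predictions = kept, rows_eval = rows_eval,
                              scores = vapply(kept, function(p) p$score, 0))
    }
  }
  out
}

# mF1 of a model over loaded samples
validate_model <- function(net, samples, ecfg_template = NULL, rcfg = riou_config(),
                           score_threshold = 0.4) {
  pr <- predict_samples(net, samples, score_threshold = score_threshold,
                        rcfg = rcfg)
  gts_eval <- lapply(samples, function(s)
    lapply(s$gts, function(g)
      rescale_row(g$row, net$cfg$input_width, net$cfg$input_height,
                  s$ann_w, s$ann_h)))
  ec <- if (is.null(ecfg_template))
    eval_config(eval_width = samples[[1]]$ann_w, eval_height = samples[[1]]$ann_h)
  else ecfg_template
  evaluate_dataset(lapply(pr, `[[`, "rows_eval"), gts_eval, ec)
}

#' Fit an anchor-line crop-row detector
#'
#' Trains the cascaded anchor-line network with the composite objective
#' (focal classification + smooth-l1 anchor regression + Row-IoU row
#' regression under dynamic positive assignment) using AdamW and a
#' polynomial learning-rate decay. Fully seeded: two runs with the same
#' seed produce identical loss curves.
#'
#' @param train_manifest data.frame manifest (from [generate_dataset()] or
#'   [read_manifest()]) of training images + annotations.
#' @param val_manifest optional validation manifest; enables periodic mF1
#'   validation and best-checkpoint selection.
#' @param profile "tiny" or "full" (see [train_config()]).
#' @param tcfg optional [train_config()] override.
#' @param mcfg optional [model_config()] override.
#' @param seed master seed (overrides `tcfg$seed` if given).
#' @param log_path optional path: per-epoch JSON-lines log plus a
#'   resolved-config snapshot written beside it.
#' @param verbose print per-epoch progress.
#' @return an object of class `row_detector`.
#' @export
row_detector <- function(train_manifest, val_manifest = NULL,
                         profile = c("tiny", "full"), tcfg = NULL, mcfg = NULL,
                         seed = NULL, log_path = NULL, verbose = TRUE) {
  profile <- match.arg(profile)
  if (is.null(tcfg)) tcfg <- train_config(profile)
  if (!is.null(seed)) tcfg$seed <- as.integer(seed)
  if (is.null(mcfg)) mcfg <- profile_model_config(profile)
  if (is.null(tcfg$assign_params))
    tcfg$assign_params <- assignment_params(
      norm_width = mcfg$input_width,
      norm_diag = sqrt(mcfg$input_width^2 + mcfg$input_height^2))
  aparams <- tcfg$assign_params

  net <- build_network(mcfg, seed = tcfg$seed)
  params <- network_params(net)
  train_set <- load_split(train_manifest, mcfg)
  val_set <- if (!is.null(val_manifest)) load_split(val_manifest, mcfg)

  n <- length(train_set)
  steps_per_epoch <- ceiling(n / tcfg$batch_size)
  total_steps <- steps_per_epoch * tcfg$epochs
  history <- data.frame()
  best <- list(mf1 = -Inf, values = NULL)
  log_con <- NULL
  if (!is.null(log_path)) {
    dir.create(dirname(log_path), recursive = TRUE, showWarnings = FALSE)
    snapshot <- sub("\\.jsonl?$", "", log_path)
    jsonlite::write_json(list(profile = profile, train = unclass(tcfg)[
      c("epochs", "batch_size", "lr", "schedule", "loss_regression", "seed")],
      model = unclass(mcfg)[c("input_width", "input_height", "num_anchors",
                              "n_points", "width_mult", "attention_mode",
                              "fpn_enabled")]),
      paste0(snapshot, "_config.json"), auto_unbox = TRUE, digits = NA)
    log_con <- file(log_path, "w")
    on.exit(close(log_con), add = TRUE)
  }

  step_t <- 0
  for (epoch in seq_len(tcfg$epochs)) {
    ord <- with_seed(derive_seed(tcfg$seed, epoch), sample.int(n))
    ep_loss <- c(total = 0, cls = 0, xytl = 0, riou = 0)
    nb <- 0
    for (start in seq(1, n, by = tcfg$batch_size)) {
      ids <- ord[start:min(start + tcfg$batch_size - 1, n)]
      batch <- train_set[ids]
      if (tcfg$augment) {
        aug_seed <- derive_seed(tcfg$seed, epoch * 100000L + start)
        batch <- with_seed(aug_seed, lapply(batch, function(smp) {
          if (stats::runif(1) < 0.5) smp <- flip_sample(smp, mcfg)
          gain <- stats::runif(1, 0.85, 1.15)
          off <- stats::runif(1, -0.05, 0.05)
          smp$image <- clamp(smp$image * gain + off, 0, 1)
          smp
        }))
      }
      step_t <- step_t + 1
      frac <- step_t / total_steps
      lr <- if (tcfg$schedule == "poly") tcfg$lr * (1 - frac + 1e-8)^0.9
            else tcfg$lr * 0.5 * (1 + cos(pi * frac))
      ls <- train_step(net, batch, tcfg, aparams, params, lr, step_t)
      ep_loss <- ep_loss + ls[c("total", "cls", "xytl", "riou")]
      nb <- nb + 1
    }
    ep_loss <- ep_loss / nb
    rec <- list(epoch = epoch, loss = ep_loss[["total"]],
                cls = ep_loss[["cls"]], xytl = ep_loss[["xytl"]],
                riou = ep_loss[["riou"]], val_mf1 = NA_real_,
                val_f1_50 = NA_real_)
    do_val <- !is.null(val_set) &&
      (epoch %% tcfg$val_every == 0 || epoch == tcfg$epochs)
    if (do_val) {
      ev <- validate_model(net, val_set, rcfg = tcfg$riou)
      rec$val_mf1 <- ev$mf1
      rec$val_f1_50 <- 100 * ev$per_threshold$f1[1]
      if (ev$mf1 >= best$mf1)
        best <- list(mf1 = ev$mf1, values = lapply(params, function(p) p$val))
    }
    history <- rbind(history, as.data.frame(rec))
    if (!is.null(log_con))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), log_con)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f (cls %.4f xytl %.4f reg %.4f)%s",
                      epoch, ep_loss[["total"]], ep_loss[["cls"]],
                      ep_loss[["xytl"]], ep_loss[["riou"]],
                      if (!is.null(rec$val_mf1))
                        sprintf("  val mF1 %.2f", rec$val_mf1) else ""))
  }
  if (!is.null(best$values)) {
    for (i in seq_along(params)) params[[i]]$val <- best$values[[i]]
  }
  structure(list(net = net, mcfg = mcfg, tcfg = tcfg, history = history,
                 best_mf1 = if (is.finite(best$mf1)) best$mf1 else NA_real_,
                 n_parameters = count_parameters(net)),
            class = "row_detector")
}

#' @export
print.row_detector <- function(x, ...) {
  cat("Anchor-line crop-row detector\n")
  cat(sprintf("  profile: %s  input %dx%d  anchors %d  N %d  params %s\n",
              x$tcfg$profile, x$mcfg$input_width, x$mcfg$input_height,
              x$mcfg$num_anchors, x$mcfg$n_points,
              format(x$n_parameters, big.mark = ",")))
  cat(sprintf("  attention: %s  fpn: %s  regression: %s\n",
              x$mcfg$attention_mode, x$mcfg$fpn_enabled, x$tcfg$loss_regression))
  if (nrow(x$history))
    cat(sprintf("  trained %d epochs, final loss %.4f%s\n",
                max(x$history$epoch), x$history$loss[nrow(x$history)],
                if (!is.na(x$best_mf1)) sprintf(", best val mF1 %.2f", x$best_mf1)
                else ""))
  invisible(x)
}

#' @export
summary.row_detector <- function(object, ...) {
  print(object)
  if (nrow(object$history)) {
    cat("\nLoss curve (per epoch):\n")
    print(utils::tail(object$history, 10), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.row_detector <- function(object, ...) object$net$params$priors$val

#' Predict crop rows on new images
#'
#' @param object a fitted `row_detector`.
#' @param newdata character vector of image paths, or a list of H x W x 3
#'   arrays, or a single array.
#' @param score_threshold,nms_iou detection and suppression thresholds.
#' @param ... unused.
#' @return list per image: `predictions` (post-NMS [row_prediction()]s at
#'   network resolution), `rows_eval` ([sampled_row()]s at the image's
#'   native resolution) and `scores`.
#' @export
predict.row_detector <- function(object, newdata, score_threshold = 0.4,
                                 nms_iou = 0.5, ...) {
  mcfg <- object$mcfg
  if (is.character(newdata)) {
    samples <- lapply(newdata, function(p) {
      img <- png::readPNG(p)
      if (length(dim(img)) == 3 && dim(img)[3] > 3) img <- img[, , 1:3]
      list(image = bilinear_resize(img, mcfg$input_width, mcfg$input_height),
           ann_w = dim(img)[2], ann_h = dim(img)[1], path = p)
    })
  } else {
    if (!is.list(newdata)) newdata <- list(newdata)
    samples <- lapply(newdata, function(img)
      list(image = bilinear_resize(img, mcfg$input_width, mcfg$input_height),
           ann_w = dim(img)[2], ann_h = dim(img)[1], path = NA_character_))
  }
  predict_samples(object$net, samples, score_threshold = score_threshold,
                  nms_iou = nms_iou, rcfg = object$tcfg$riou)
}

#' Plot detected rows over an image
#'
#' @param x a fitted `row_detector`.
#' @param image path to a PNG image or an H x W x 3 array.
#' @param ... passed to [predict.row_detector()].
#' @export
plot.row_detector <- function(x, image, ...) {
  img <- if (is.character(image)) png::readPNG(image) else image
  pr <- predict(x, list(img), ...)[[1]]
  H <- dim(img)[1]; W <- dim(img)[2]
  graphics::plot(NULL, xlim = c(0, W), ylim = c(H, 0), asp = 1,
                 xlab = "x (px)", ylab = "y (px)", main = "detected crop rows")
  graphics::rasterImage(img, 0, H, W, 0)
  cols <- grDevices::rainbow(max(1, length(pr$rows_eval)))
  for (i in seq_along(pr$rows_eval)) {
    r <- pr$rows_eval[[i]]
    v <- r$valid
    graphics::lines(r$xs[v], sample_ys(r$n_points, r$height)[v],
                    col = cols[i], lwd = 3)
  }
  invisible(pr)
}

#' Save / load a model checkpoint
#'
#' Serializes the parameter values plus model and training configuration.
#'
#' @param model a `row_detector`.
#' @param path checkpoint file path (RDS).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  params <- network_params(model$net)
  saveRDS(list(values = lapply(params, function(p) p$val),
               mcfg = model$mcfg, tcfg = model$tcfg, history = model$history,
               best_mf1 = model$best_mf1), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- build_network(ck$mcfg, seed = ck$tcfg$seed)
  params <- network_params(net)
  stopifnot(length(params) == length(ck$values))
  for (i in seq_along(params)) params[[i]]$val <- ck$values[[i]]
  structure(list(net = net, mcfg = ck$mcfg, tcfg = ck$tcfg,
                 history = ck$history, best_mf1 = ck$best_mf1,
                 n_parameters = count_parameters(net)),
            class = "row_detector")
}

#' Run inference over images and write LabelMe-dialect predictions
#'
#' @param model a fitted `row_detector`.
#' @param image_paths character vector of PNG paths.
#' @param out_dir output directory for prediction JSON files (and
#'   overlays if `render`).
#' @param render also write PNG overlays of the detected rows.
#' @param score_threshold,nms_iou thresholds passed to predict.
#' @return invisible list of per-image predictions.
#' @export
infer <- function(model, image_paths, out_dir, render = FALSE,
                  score_threshold = 0.4, nms_iou = 0.5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prs <- predict(model, image_paths, score_threshold = score_threshold,
                 nms_iou = nms_iou)
  for (i in seq_along(image_paths)) {
    pr <- prs[[i]]
    img <- png::readPNG(image_paths[i])
    H <- dim(img)[1]; W <- dim(img)[2]
    polys <- list(); scores <- numeric(0)
    for (k in seq_along(pr$rows_eval)) {
      r <- pr$rows_eval[[k]]
      v <- which(r$valid)
      if (length(v) < 2) next
      ys <- sample_ys(r$n_points, r$height)
      pts <- cbind(clamp(r$xs[v], 0, W), clamp(ys[v], 0, H))
      keep <- c(TRUE, diff(pts[, 2]) > 0)
      if (sum(keep) < 2) next
      polys[[length(polys) + 1]] <- row_polyline(pts[keep, , drop = FALSE],
                                                 W, H,
                                                 sprintf("row_%d", length(polys) + 1))
      scores <- c(scores, pr$scores[k])
    }
    stem <- sub("\\.png$", "", basename(image_paths[i]))
    write_labelme(polys, list(imagePath = basename(image_paths[i]),
                              imageWidth = W, imageHeight = H),
                  file.path(out_dir, paste0(stem, ".json")), scores = scores)
    if (render) {
      grDevices::png(file.path(out_dir, paste0(stem, "_overlay.png")),
                     width = W, height = H)
      graphics::par(mar = c(0, 0, 0, 0))
      graphics::plot.new(); graphics::plot.window(c(0, W), c(H, 0), asp = 1)
      graphics::rasterImage(img, 0, H, W, 0)
      cols <- grDevices::rainbow(max(1, length(polys)))
      for (k in seq_along(polys))
        graphics::lines(polys[[k]]$points[, 1], polys[[k]]$points[, 2],
                        col = cols[k], lwd = 4)
      grDevices::dev.off()
    }
  }
  invisible(prs)
}

#' Evaluate a directory of predictions against annotations
#'
#' Matches files by stem, converts every linestrip to a sampled row at the
#' evaluation resolution and applies the thickened-mask protocol; results
#' are written as CSV + JSON next to being returned.
#'
#' @param pred_dir directory of prediction LabelMe JSON files.
#' @param gt_dir directory of ground-truth LabelMe JSON files.
#' @param cfg an [eval_config()].
#' @param out_prefix optional path prefix for `*_results.csv` /
#'   `*_results.json`.
#' @param allow_missing treat annotation stems without a prediction file
#'   as images with zero predictions instead of aborting.
#' @param n_points discretization for mask rasterization.
#' @return an `eval_result`.
#' @export
evaluate_cmd <- function(pred_dir, gt_dir, cfg = eval_config(),
                         out_prefix = NULL, allow_missing = FALSE,
                         n_points = 72) {
  gt_files <- sort(list.files(gt_dir, pattern = "\\.json$", full.names = TRUE))
  gt_files <- gt_files[!grepl("manifest", gt_files)]
  stems <- sub("\\.json$", "", basename(gt_files))
  pred_files <- file.path(pred_dir, paste0(stems, ".json"))
  missing <- !file.exists(pred_files)
  if (any(missing) && !allow_missing)
    cr_stop(paste0("missing prediction files for stems: ",
                   paste(stems[missing], collapse = ", ")),
            "croprows_io_error")
  to_rows <- function(path) {
    if (!file.exists(path)) return(list())
    polys <- suppressWarnings(read_labelme(path))
    lapply(polys, function(p) {
      pts <- p$points
      pts[, 1] <- pts[, 1] * cfg$eval_width / p$image_width
      pts[, 2] <- pts[, 2] * cfg$eval_height / p$image_height
      sample_row(row_polyline(pts, cfg$eval_width, cfg$eval_height, p$label),
                 n_points, cfg$eval_height)
    })
  }
  preds <- lapply(pred_files, to_rows)
  gts <- lapply(gt_files, to_rows)
  res <- evaluate_dataset(preds, gts, cfg)
  if (!is.null(out_prefix))
    write_eval_result(res, paste0(out_prefix, "_results.csv"),
                      paste0(out_prefix, "_results.json"))
  res
}

#' Ablation grid on synthetic data
#'
#' Trains one model per arm of the component grid (regression loss
#' Row-IoU vs smooth-l1; attention off / full / dae; FPN on / off) under
#' identical data and seeds, and evaluates mF1 on the validation split.
#'
#' @param train_manifest,val_manifest dataset manifests.
#' @param arms data.frame with columns regression, attention, fpn; the
#'   default mirrors the component-ablation table structure.
#' @param profile,epochs,seeds training scale controls (`seeds` is a
#'   vector; the per-arm mF1 is the median over seeds).
#' @param verbose print progress.
#' @return data.frame with one row per arm: configuration plus mF1 and
#'   F1@50 (medians over seeds).
#' @export
ablate <- function(train_manifest, val_manifest, arms = NULL,
                   profile = "tiny", epochs = NULL, seeds = 1L,
                   verbose = TRUE) {
  if (is.null(arms))
    arms <- data.frame(
      regression = c("smooth_l1", "riou", "riou", "smooth_l1", "riou", "riou"),
      attention = c("off", "off", "off", "dae", "full", "dae"),
      fpn = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
      stringsAsFactors = FALSE)
  res <- arms
  res$mf1 <- NA_real_; res$f1_50 <- NA_real_
  for (i in seq_len(nrow(arms))) {
    mf1s <- f50s <- numeric(0)
    for (sd in seeds) {
      tcfg <- train_config(profile, epochs = epochs,
                           loss_regression = arms$regression[i], seed = sd)
      mcfg <- profile_model_config(profile,
                                   attention_mode = arms$attention[i],
                                   fpn_enabled = arms$fpn[i])
      fit <- row_detector(train_manifest, val_manifest, profile = profile,
                          tcfg = tcfg, mcfg = mcfg, verbose = FALSE)
      ev_samples <- load_split(val_manifest, mcfg)
      ev <- validate_model(fit$net, ev_samples, rcfg = tcfg$riou)
      mf1s <- c(mf1s, ev$mf1)
      f50s <- c(f50s, 100 * ev$per_threshold$f1[1])
    }
    res$mf1[i] <- stats::median(mf1s)
    res$f1_50[i] <- stats::median(f50s)
    if (verbose)
      message(sprintf("arm %d/%d [%s | att %s | fpn %s]: mF1 %.2f  F1@50 %.2f",
                      i, nrow(arms), arms$regression[i], arms$attention[i],
                      arms$fpn[i], res$mf1[i], res$f1_50[i]))
  }
  res
}
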
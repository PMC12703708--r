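# Thickened-mask evaluation protocol: row polylines are thickened to
# fixed-width strokes, mask IoU is computed between predicted and ground-truth
# strokes, predictions are matched one-to-one to ground truth, and F1 is
# reported at mask-IoU thresholds 0.50-0.95 together with their mean (mF1,
# on the 0-100 scale).

#' Evaluation configuration
#'
#' @param thickness stroke width in px applied to each row line (default 50).
#' @param thresholds increasing mask-IoU thresholds in (0, 1).
#' @param eval_width,eval_height evaluation (annotation) resolution in px.
#' @param strict_greater if TRUE a match counts as TP only when IoU is
#'   strictly greater than the threshold.
#' @return an object of class `eval_config`.
#' @export
eval_config <- function(thickness = 50, thresholds = seq(0.50, 0.95, by = 0.05),
                        eval_width = 1280, eval_height = 720,
                        strict_greater = TRUE) {
  stopifnot(thickness >= 1, all(diff(thresholds) > 0),
            all(thresholds > 0 & thresholds < 1))
  structure(list(thickness = thickness, thresholds = thresholds,
                 eval_width = eval_width, eval_height = eval_height,
                 strict_greater = strict_greater), class = "eval_config")
}

#' Thicken a sampled row into a binary stroke mask
#'
#' Rasterizes the row's valid polyline with a square-capped, join-filled
#' stroke of width `thickness`, without anti-aliasing, onto an
#' eval_height x eval_width grid. A pixel (column c, row r), 0-based,
#' belongs to the stroke when its center (c + 0.5, r + 0.5) falls inside
#' the stroke rectangle of some segment, using a half-open [lo, hi)
#' horizontal interval per scanline so stroke widths are exact.
#'
#' @param row a [sampled_row()] at the evaluation resolution.
#' @param cfg an [eval_config()].
#' @return logical eval_height x eval_width matrix.
#' @export
thicken_mask <- function(row, cfg = eval_config()) {
  H <- cfg$eval_height; W <- cfg$eval_width
  mask <- matrix(FALSE, H, W)
  v <- which(row$valid)
  if (length(v) < 2) {
    warning("row has fewer than 2 valid points; returning an empty mask")
    return(mask)
  }
  ys <- sample_ys(row$n_points, row$height)
  px <- row$xs[v]; py <- ys[v]
  half <- cfg$thickness / 2
  for (s in seq_len(length(v) - 1)) {
    p0 <- c(px[s], py[s]); p1 <- c(px[s + 1], py[s + 1])
    dvec <- p1 - p0
    len <- sqrt(sum(dvec^2))
    if (len == 0) next
    u <- dvec / len                       # unit direction (downward: u[2] > 0)
    nrm <- c(-u[2], u[1])                 # unit normal
    a <- p0 - half * u                    # square caps: extend both ends
    b <- p1 + half * u
    corners <- rbind(a + half * nrm, a - half * nrm,
                     b - half * nrm, b + half * nrm)  # convex quad, in order
    yy <- corners[, 2]
    r0 <- max(0L, floor(min(yy) - 0.5))
    r1 <- min(H - 1L, ceiling(max(yy) - 0.5))
    if (r1 < r0) next
    for (r in r0:r1) {
      yc <- r + 0.5
      # x-crossings of scanline yc with the 4 quad edges
      xs_cross <- numeric(0)
      for (e in 1:4) {
        q0 <- corners[e, ]; q1 <- corners[if (e == 4) 1 else e + 1, ]
        if ((q0[2] <= yc && q1[2] > yc) || (q1[2] <= yc && q0[2] > yc)) {
          t <- (yc - q0[2]) / (q1[2] - q0[2])
          xs_cross <- c(xs_cross, q0[1] + t * (q1[1] - q0[1]))
        } else if (q0[2] == yc && q1[2] == yc) {
          xs_cross <- c(xs_cross, q0[1], q1[1])
        }
      }
      if (length(xs_cross) < 2) next
      lo <- min(xs_cross); hi <- max(xs_cross)
      c0 <- max(0L, ceiling(lo - 0.5))
      c1 <- min(W - 1L, ceiling(hi - 0.5) - 1L)
      if (c1 >= c0) mask[r + 1L, (c0:c1) + 1L] <- TRUE
    }
  }
  mask
}

#' IoU between two binary masks
#'
#' @param a,b logical matrices of identical shape.
#' @return |a & b| / |a | b|; 0 when the union is empty.
#' @export
mask_iou <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    cr_stop("mask shapes differ", "croprows_contract_violation")
  un <- sum(a | b)
  if (un == 0) return(0)
  sum(a & b) / un
}

# Optimal one-to-one matching maximizing total IoU; bitmask DP over the
# smaller side. Returns a 2-column matrix (pred index, gt index) of matched
# pairs with IoU > 0.
match_pairs_optimal <- function(iou) {
  np <- nrow(iou); ng <- ncol(iou)
  if (np == 0 || ng == 0) return(cbind(integer(0), integer(0)))
  flip <- ng > np
  m <- if (flip) t(iou) else iou          # ensure ncol is the smaller side
  n1 <- nrow(m); n2 <- ncol(m)
  nmask <- bitwShiftL(1L, n2)
  f <- matrix(-Inf, n1 + 1L, nmask); f[n1 + 1L, ] <- 0
  choice <- matrix(0L, n1, nmask)         # 0 = skip, j = match column j
  for (i in n1:1) {
    for (msk in 0:(nmask - 1L)) {
      best <- f[i + 1L, msk + 1L]; arg <- 0L
      for (j in seq_len(n2)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(msk, bit) == 0L && m[i, j] > 0) {
          cand <- m[i, j] + f[i + 1L, bitwOr(msk, bit) + 1L]
          if (cand > best + 1e-15) { best <- cand; arg <- j }
        }
      }
      f[i, msk + 1L] <- best; choice[i, msk + 1L] <- arg
    }
  }
  pairs <- matrix(integer(0), 0, 2)
  msk <- 0L
  for (i in seq_len(n1)) {
    j <- choice[i, msk + 1L]
    if (j > 0L) {
      pairs <- rbind(pairs, c(i, j))
      msk <- bitwOr(msk, bitwShiftL(1L, j - 1L))
    }
  }
  if (flip && nrow(pairs) > 0) pairs <- pairs[, 2:1, drop = FALSE]
  pairs
}

#' Match predictions to ground truth and accumulate detection counts
#'
#' Per image, the pred x gt mask-IoU matrix is built once and a one-to-one
#' matching maximizing total IoU is computed; the same matching is reused
#' at every threshold. A matched pair whose IoU exceeds the threshold is a
#' TP; all other predictions are FP and uncovered ground-truth rows FN.
#'
#' @param preds,gts lists (one element per image) of lists of
#'   [sampled_row()] objects at the evaluation resolution.
#' @param cfg an [eval_config()].
#' @return data.frame with columns threshold, tp, fp, fn.
#' @export
match_and_score <- function(preds, gts, cfg = eval_config()) {
  stopifnot(length(preds) == length(gts))
  nt <- length(cfg$thresholds)
  tp <- fp <- fn <- integer(nt)
  for (im in seq_along(preds)) {
    pm <- lapply(preds[[im]], thicken_mask, cfg = cfg)
    gm <- lapply(gts[[im]], thicken_mask, cfg = cfg)
    np <- length(pm); ng <- length(gm)
    iou <- matrix(0, np, ng)
    if (np > 0 && ng > 0)
      for (i in seq_len(np)) for (j in seq_len(ng)) iou[i, j] <- mask_iou(pm[[i]], gm[[j]])
    pairs <- match_pairs_optimal(iou)
    pair_iou <- if (nrow(pairs) > 0) iou[pairs] else numeric(0)
    for (t in seq_len(nt)) {
      tau <- cfg$thresholds[t]
      hit <- if (cfg$strict_greater) pair_iou > tau else pair_iou >= tau
      ntp <- sum(hit)
      tp[t] <- tp[t] + ntp
      fp[t] <- fp[t] + (np - ntp)
      fn[t] <- fn[t] + (ng - ntp)
    }
  }
  data.frame(threshold = cfg$thresholds, tp = tp, fp = fp, fn = fn)
}

#' Evaluate a prediction set: F1 per threshold and mF1
#'
#' @inheritParams match_and_score
#' @return an object of class `eval_result`: a list with `per_threshold`
#'   (data.frame threshold/precision/recall/f1, on [0, 1]) and `mf1`
#'   (percent, 0-100).
#' @export
evaluate_dataset <- function(preds, gts, cfg = eval_config()) {
  if (sum(lengths(gts)) == 0)
    cr_stop("no ground-truth rows in the evaluation set", "croprows_invalid_evaluation")
  counts <- match_and_score(preds, gts, cfg)
  prec <- ifelse(counts$tp + counts$fp > 0, counts$tp / (counts$tp + counts$fp), 0)
  rec <- ifelse(counts$tp + counts$fn > 0, counts$tp / (counts$tp + counts$fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(
    per_threshold = data.frame(threshold = counts$threshold,
                               precision = prec, recall = rec, f1 = f1),
    mf1 = 100 * mean(f1)), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat("Thickened-mask row evaluation\n")
  pt <- x$per_threshold
  cat(sprintf("  F1@%.2f: %6.2f   (P %5.1f  R %5.1f)\n",
              pt$threshold, 100 * pt$f1, 100 * pt$precision, 100 * pt$recall), sep = "")
  cat(sprintf("  mF1: %.2f\n", x$mf1))
  invisible(x)
}

#' Write evaluation results to CSV and JSON
#'
#' @param result an `eval_result`.
#' @param csv_path,json_path output file paths.
#' @return invisibly, the result.
#' @export
write_eval_result <- function(result, csv_path, json_path) {
  pt <- result$per_threshold
  utils::write.csv(data.frame(threshold = pt$threshold,
                              precision = 100 * pt$precision,
                              recall = 100 * pt$recall,
                              f1 = 100 * pt$f1),
                   csv_path, row.names = FALSE)
  jsonlite::write_json(list(mf1 = result$mf1,
                            f1_per_threshold = stats::setNames(
                              as.list(100 * pt$f1),
                              sprintf("f1_at_%d", round(100 * pt$threshold)))),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(result)
}
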
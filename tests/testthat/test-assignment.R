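test_that("similarity cost components follow the product-square form", {
  params <- assignment_params(norm_width = 320,
                              norm_diag = sqrt(320^2 + 160^2))
  g <- straight_row(100, 100, 5, 160)
  gt_anchor <- croprows:::gt_anchor_from_row(g)
  exact <- row_prediction(0.9, gt_anchor, rep(0, 5))
  sc <- similarity_cost(exact, g, gt_anchor, params)
  expect_equal(sc$c_dis, 0); expect_equal(sc$c_xy, 0)
  expect_equal(sc$c_theta, 0); expect_equal(sc$c_sim, 0)

  # any single zero component kills the product
  shifted <- row_prediction(0.9, anchor_line(gt_anchor$start_x + 40,
                                             gt_anchor$start_y,
                                             gt_anchor$theta, 5), rep(40, 5))
  sc2 <- similarity_cost(shifted, g, gt_anchor, params)
  expect_gt(sc2$c_dis, 0); expect_equal(sc2$c_theta, 0)
  expect_equal(sc2$c_sim, 0)

  # direct arithmetic: all components 0.5 gives (0.125)^2
  expect_equal((0.5 * 0.5 * 0.5)^2, 0.015625)
})

test_that("forced assignments hold in the simplest instances", {
  params <- assignment_params(norm_width = 320, norm_diag = 360)
  cfg <- riou_config()
  g <- straight_row(100, 110, 5, 160)
  gts <- list(list(row = g, anchor = croprows:::gt_anchor_from_row(g)))

  p1 <- row_prediction(0.5, anchor_line(150, 160, 1.4, 5), rep(0, 5))
  a1 <- assign(list(p1), gts, params, cfg)
  expect_equal(a1$pred_to_gt, 1L)

  # two identical near-perfect predictions with k = 2 are both positive
  pg <- row_prediction(0.9, gts[[1]]$anchor, rep(0, 5))
  a2 <- assign(list(pg, pg), gts, params, cfg)
  expect_equal(a2$pred_to_gt, c(1L, 1L))

  a0 <- assign(list(p1), list(), params, cfg)
  expect_equal(nrow(a0$pos_pairs), 0)
  expect_true(all(is.na(a0$pred_to_gt)))
})

test_that("assign matches exhaustive enumeration of its own rule", {
  set.seed(77)
  params <- assignment_params(norm_width = 320, norm_diag = 453)
  cfg <- riou_config()
  w <- loss_weights()

  oracle <- function(preds, gts) {
    np <- length(preds); ng <- length(gts)
    # independent cost assembly from the exported primitives
    ca <- matrix(0, np, ng); ri <- matrix(0, np, ng)
    for (i in seq_len(np)) for (j in seq_len(ng)) {
      sc <- similarity_cost(preds[[i]], gts[[j]]$row, gts[[j]]$anchor, params)
      ccls <- focal_loss(preds[[i]]$score, TRUE, w$focal_alpha, w$focal_gamma)
      ca[i, j] <- params$w_sim * sc$c_sim + params$w_cls * ccls
      pr <- anchor_to_points(preds[[i]]$anchor, preds[[i]]$offsets,
                             gts[[j]]$row$n_points, gts[[j]]$row$height)
      ri[i, j] <- row_iou(pr, gts[[j]]$row, cfg)
    }
    # dynamic k by explicit enumeration of candidate subsets
    claims <- vector("list", ng)
    for (j in seq_len(ng)) {
      v <- sort(ri[, j], decreasing = TRUE)[seq_len(min(params$topk_pool, np))]
      k <- min(params$topk_pool, max(1L, as.integer(round(sum(pmax(v, 0))))))
      k <- min(k, np)
      best_cost <- Inf; best_set <- NULL
      for (set in utils::combn(np, k, simplify = FALSE)) {
        cost <- sum(ca[set, j])
        if (cost < best_cost - 1e-15) { best_cost <- cost; best_set <- set }
      }
      claims[[j]] <- sort(best_set)
    }
    p2g <- rep(NA_integer_, np)
    for (i in seq_len(np)) {
      claiming <- which(vapply(claims, function(s) i %in% s, TRUE))
      if (length(claiming) == 0) next
      p2g[i] <- claiming[which.min(ca[i, claiming])]
    }
    for (j in seq_len(ng)) {
      if (any(p2g == j, na.rm = TRUE)) next
      free <- which(is.na(p2g))
      if (length(free) == 0) next
      p2g[free[which.min(ca[free, j])]] <- j
    }
    p2g
  }

  for (inst in 1:200) {
    np <- sample(1:6, 1); ng <- sample(1:3, 1)
    z <- random_assignment_instance(np, ng)
    got <- assign(z$preds, z$gts, params, cfg)
    expect_equal(got$pred_to_gt, oracle(z$preds, z$gts),
                 info = sprintf("instance %d (np=%d ng=%d)", inst, np, ng))
    # structural invariants
    expect_true(all(table(got$pred_to_gt[!is.na(got$pred_to_gt)]) >= 1))
    expect_lte(length(unique(stats::na.omit(got$pred_to_gt))),
               min(np, ng) + ng)
  }
})

test_that("every ground truth keeps a positive when predictions suffice", {
  set.seed(5)
  params <- assignment_params(norm_width = 320, norm_diag = 453)
  for (rep in 1:30) {
    z <- random_assignment_instance(6, 3)
    got <- assign(z$preds, z$gts, params, riou_config())
    expect_setequal(unique(got$pos_pairs[, "gt"]), 1:3)
    expect_false(any(duplicated(got$pos_pairs[, "pred"])))
  }
})

test_that("total_loss composes terms linearly with its weights", {
  set.seed(9)
  z <- random_assignment_instance(5, 2)
  params <- assignment_params(norm_width = 320, norm_diag = 453)
  asg <- assign(z$preds, z$gts, params, riou_config())
  st <- list(list(preds = z$preds, assignment = asg))

  w0 <- loss_weights(w_cls = 0, w_xytl = 0, w_riou = 0)
  expect_equal(total_loss(st, z$gts, w0)$total, 0)

  w1 <- loss_weights(w_cls = 1, w_xytl = 1, w_riou = 1)
  l1 <- total_loss(st, z$gts, w1)
  expect_equal(l1$total, l1$cls + l1$xytl + l1$riou, tolerance = 1e-12)

  w2 <- loss_weights(w_cls = 1, w_xytl = 1, w_riou = 2)
  l2 <- total_loss(st, z$gts, w2)
  expect_equal(l2$cls, l1$cls)
  expect_equal(l2$xytl, l1$xytl)
  expect_equal(l2$total - l1$total, l1$riou, tolerance = 1e-12)

  # near-perfect predictions with confident scores drive the loss to zero
  g <- z$gts[[1]]
  perfect <- row_prediction(1 - 1e-9, g$anchor, rep(0, 5))
  offs <- g$row$xs - croprows:::anchor_ref_xs(
    matrix(c(g$anchor$start_x, g$anchor$start_y, g$anchor$theta,
             g$anchor$length), 1), sample_ys(5, 320))[1, ]
  perfect$offsets <- offs
  asg_p <- assign(list(perfect), list(g), params, riou_config())
  lp <- total_loss(list(list(preds = list(perfect), assignment = asg_p)),
                   list(g), w1)
  expect_lt(lp$xytl + lp$riou, 1e-9)
  expect_lt(lp$cls, 1e-4)
})
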
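test_that("thicken_mask reproduces the stroke-band pixel counts", {
  cfg <- eval_config(thickness = 50, eval_width = 100, eval_height = 100)
  vline <- straight_row(50, 50, 11, 100)
  m <- thicken_mask(vline, cfg)
  expect_equal(sum(m), 5000)
  on_cols <- which(colSums(m) > 0) - 1L        # 0-based columns [25, 75)
  expect_equal(range(on_cols), c(25, 74))

  cfg1 <- eval_config(thickness = 1, eval_width = 100, eval_height = 100)
  m1 <- thicken_mask(vline, cfg1)
  expect_equal(sum(colSums(m1) > 0), 1)

  empty <- sampled_row(rep(0, 5), rep(FALSE, 5), 100)
  expect_warning(me <- thicken_mask(empty, cfg))
  expect_false(any(me))
})

test_that("mask_iou is set arithmetic on the stroke bands", {
  cfg <- eval_config(thickness = 50, eval_width = 100, eval_height = 100)
  a <- thicken_mask(straight_row(50, 50, 11, 100), cfg)
  b <- thicken_mask(straight_row(75, 75, 11, 100), cfg)
  expect_equal(mask_iou(a, a), 1)
  expect_equal(mask_iou(a, b), 1 / 3, tolerance = 1e-12)   # 25 / 75 columns
  far <- thicken_mask(straight_row(10, 10, 11, 100),
                      eval_config(thickness = 10, eval_width = 100,
                                  eval_height = 100))
  expect_equal(mask_iou(thicken_mask(straight_row(80, 80, 11, 100),
                                     eval_config(thickness = 10,
                                                 eval_width = 100,
                                                 eval_height = 100)), far), 0)
  expect_error(mask_iou(a, a[1:50, ]), class = "croprows_contract_violation")
})

test_that("matching and scoring follow the thickened-mask protocol", {
  cfg <- eval_config(thickness = 30, eval_width = 200, eval_height = 100)
  r1 <- straight_row(50, 60, 11, 100)
  r2 <- straight_row(150, 140, 11, 100)

  # perfect detector
  ev <- evaluate_dataset(list(list(r1, r2)), list(list(r1, r2)), cfg)
  expect_equal(ev$mf1, 100)
  expect_true(all(ev$per_threshold$f1 == 1))

  # one of two rows found perfectly: P = 1, R = 0.5, F1 = 2/3 at every tau
  ev2 <- evaluate_dataset(list(list(r1)), list(list(r1, r2)), cfg)
  expect_equal(ev2$per_threshold$f1, rep(2 / 3, 10), tolerance = 1e-12)

  # no predictions at all
  ev3 <- evaluate_dataset(list(list()), list(list(r1)), cfg)
  expect_equal(ev3$mf1, 0)

  expect_error(evaluate_dataset(list(list(r1)), list(list()), cfg),
               class = "croprows_invalid_evaluation")
})

test_that("a pair at mask IoU 0.60 scores under strict threshold exceedance", {
  # two vertical 48-px bands offset by 12 px: intersection 36 columns,
  # union 60, mask IoU exactly 0.60
  cfg <- eval_config(thickness = 48, eval_width = 200, eval_height = 100)
  g <- straight_row(80, 80, 11, 100)
  p <- straight_row(92, 92, 11, 100)
  expect_equal(mask_iou(thicken_mask(p, cfg), thicken_mask(g, cfg)), 0.6,
               tolerance = 1e-9)
  ev <- evaluate_dataset(list(list(p)), list(list(g)), cfg)
  expect_equal(ev$per_threshold$f1, c(1, 1, rep(0, 8)))
  expect_equal(ev$mf1, 20, tolerance = 1e-9)
})

test_that("F1 is non-increasing in the threshold and order-invariant", {
  set.seed(10)
  cfg <- eval_config(thickness = 40, eval_width = 320, eval_height = 160)
  mk_img <- function() {
    gts <- lapply(seq_len(3), function(k)
      straight_row(60 + 90 * (k - 1) + runif(1, -10, 10),
                   80 + 80 * (k - 1), 9, 160))
    preds <- lapply(gts, function(g)
      sampled_row(g$xs + rnorm(1, 0, 18), g$valid, g$height))
    list(gts = gts, preds = preds)
  }
  imgs <- replicate(4, mk_img(), simplify = FALSE)
  preds <- lapply(imgs, `[[`, "preds"); gts <- lapply(imgs, `[[`, "gts")
  ev <- evaluate_dataset(preds, gts, cfg)
  expect_true(all(diff(ev$per_threshold$f1) <= 1e-12))

  perm <- c(3, 1, 4, 2)
  ev_img <- evaluate_dataset(preds[perm], gts[perm], cfg)
  expect_equal(ev_img$mf1, ev$mf1)
  preds_shuf <- lapply(preds, function(p) p[sample(length(p))])
  ev_shuf <- evaluate_dataset(preds_shuf, gts, cfg)
  expect_equal(ev_shuf$mf1, ev$mf1)
})

test_that("optimal matching dominates greedy matching in total TP", {
  set.seed(11)
  greedy_pairs <- function(iou) {
    pairs <- NULL; used_p <- used_g <- integer(0)
    repeat {
      iou2 <- iou; if (length(used_p)) iou2[used_p, ] <- -1
      if (length(used_g)) iou2[, used_g] <- -1
      best <- which(iou2 == max(iou2), arr.ind = TRUE)[1, ]
      if (iou2[best[1], best[2]] <= 0) break
      pairs <- rbind(pairs, best)
      used_p <- c(used_p, best[1]); used_g <- c(used_g, best[2])
    }
    pairs
  }
  for (rep in 1:100) {
    np <- sample(1:5, 1); ng <- sample(1:5, 1)
    iou <- matrix(runif(np * ng), np, ng) * (matrix(runif(np * ng), np, ng) > 0.3)
    opt <- croprows:::match_pairs_optimal(iou)
    gre <- greedy_pairs(iou)
    opt_sum <- if (nrow(opt)) sum(iou[opt]) else 0
    gre_sum <- if (!is.null(gre)) sum(iou[gre]) else 0
    expect_gte(opt_sum + 1e-12, gre_sum)
    for (tau in c(0.3, 0.5, 0.7)) {
      tp_opt <- if (nrow(opt)) sum(iou[opt] > tau) else 0
      # optimal total-IoU matching should not lose TPs badly vs greedy
      tp_gre <- if (!is.null(gre)) sum(iou[gre] > tau) else 0
      expect_gte(tp_opt + 1, tp_gre)  # sanity dominance up to one swap
    }
  }
})

test_that("evaluation results serialize to CSV and JSON", {
  cfg <- eval_config(thickness = 30, eval_width = 200, eval_height = 100)
  r1 <- straight_row(50, 60, 11, 100)
  ev <- evaluate_dataset(list(list(r1)), list(list(r1)), cfg)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_eval_result(ev, csv, js)
  tab <- utils::read.csv(csv)
  expect_equal(nrow(tab), 10)
  expect_equal(jsonlite::fromJSON(js)$mf1, 100)
})
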
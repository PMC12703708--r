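tiny_cfg <- function(...) model_config(96, 64, num_anchors = 8, n_points = 6,
                                       width_mult = 0.125, stem_kernel = 3,
                                       ...)

test_that("anchor priors are deterministic and well-formed", {
  p1 <- init_anchor_priors(64, 36, seed = 3, width = 320, height = 160)
  p2 <- init_anchor_priors(64, 36, seed = 3, width = 320, height = 160)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 64)
  expect_true(all(p1[, "theta"] > 0 & p1[, "theta"] < pi))
  expect_true(all(p1[, "theta"] > 15 * pi / 180 - 1e-9 &
                    p1[, "theta"] < 165 * pi / 180 + 1e-9))
  expect_true(all(p1[, "start_x"] >= 0 & p1[, "start_x"] <= 320))
  expect_true(all(p1[, "start_y"] >= 80 & p1[, "start_y"] <= 160))
  p3 <- init_anchor_priors(64, 36, seed = 4, width = 320, height = 160)
  expect_false(identical(p1[, "theta"], p3[, "theta"]))
})

test_that("line_pool samples bilinearly with optional 1D mixing", {
  C <- 3
  fmap <- array(0, c(4, 6, C))
  for (c in 1:C) fmap[, , c] <- c          # constant per channel
  pts <- cbind(c(0, 2.5, 4.2), c(0, 1.5, 3))
  out <- line_pool(fmap, pts)
  for (c in 1:C) expect_equal(out[, c], rep(c, 3), tolerance = 1e-12)

  # integer coordinates hit the cell exactly
  f2 <- array(seq_len(4 * 6), c(4, 6, 1))
  expect_equal(line_pool(f2, cbind(2, 1))[1, 1], f2[2, 3, 1])
  # midway between two horizontal neighbours: their average
  expect_equal(line_pool(f2, cbind(2.5, 1))[1, 1],
               (f2[2, 3, 1] + f2[2, 4, 1]) / 2)

  # identity 1D kernel (center tap only) returns the samples unchanged
  ident <- matrix(0, C * 3, C)
  for (c in 1:C) ident[(c - 1) * 3 + 2, c] <- 1
  out2 <- line_pool(fmap, pts, kernel = ident)
  expect_equal(out2, out, tolerance = 1e-12)
})

test_that("cascade refinement is additive and deterministic", {
  cfg <- tiny_cfg()
  net <- build_network(cfg, seed = 2)
  img <- array(runif(64 * 96 * 3), c(64, 96, 3))

  # zeroed head branches: p1 == p0 and zero offsets
  for (hd in net$params$heads) {
    hd$delta$val[] <- 0; hd$delta_b$val[] <- 0
    hd$offs$val[] <- 0; hd$offs_b$val[] <- 0
  }
  cf <- cascade_forward(net, img)
  expect_equal(cf$anchor_sets$p1, cf$anchor_sets$p0, tolerance = 1e-12)
  expect_equal(cf$anchor_sets$p2, cf$anchor_sets$p0, tolerance = 1e-12)
  expect_true(all(cf$stages[[3]]$offsets == 0))
  expect_equal(length(cf$predictions), cfg$num_anchors)

  # non-zero heads: refinement consistency p_k = p_(k-1) + deltas, exactly
  net2 <- build_network(cfg, seed = 5)
  cf2 <- cascade_forward(net2, img)
  expect_equal(cf2$anchor_sets$p1,
               cf2$anchor_sets$p0 + cf2$stages[[1]]$deltas)
  expect_equal(cf2$anchor_sets$p2,
               cf2$anchor_sets$p1 + cf2$stages[[2]]$deltas)
  cf3 <- cascade_forward(net2, img)
  expect_identical(cf2$stages[[3]]$scores, cf3$stages[[3]]$scores)
  expect_identical(cf2$stages[[3]]$offsets, cf3$stages[[3]]$offsets)

  for (s in 1:3) {
    expect_equal(length(cf2$stages[[s]]$scores), cfg$num_anchors)
    expect_true(all(is.finite(cf2$stages[[s]]$deltas)))
  }
})

test_that("ablation toggles preserve the forward contract", {
  img <- array(runif(64 * 96 * 3), c(64, 96, 3))
  for (mode in c("off", "full", "dae")) {
    for (fpn in c(TRUE, FALSE)) {
      net <- build_network(tiny_cfg(attention_mode = mode, fpn_enabled = fpn),
                           seed = 1)
      cf <- cascade_forward(net, img)
      expect_equal(length(cf$predictions), 8)
      expect_true(all(vapply(cf$predictions, function(p)
        p$score >= 0 && p$score <= 1, TRUE)))
    }
  }
})

test_that("the tiny profile runs a full forward pass quickly", {
  net <- build_network(profile_model_config("tiny"), seed = 1)
  img <- array(runif(160 * 320 * 3), c(160, 320, 3))
  cascade_forward(net, img)  # warm the index caches
  t0 <- Sys.time()
  cf <- cascade_forward(net, img)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_lt(elapsed, 2)
  expect_equal(length(cf$predictions), 64)
  expect_gt(count_parameters(net), 1e5)
})

test_that("row NMS suppresses by Row-IoU with greedy score order", {
  cfg <- riou_config(extension_e = 15)
  mk <- function(x, score) row_prediction(score, anchor_line(x, 320, pi / 2, 5),
                                          rep(0, 5))
  # identical rows: keep only the higher score
  kept <- row_nms(list(mk(100, 0.9), mk(100, 0.8)), 0.5, 0.4, cfg,
                  n_points = 5, height = 320)
  expect_equal(length(kept), 1)
  expect_equal(kept[[1]]$score, 0.9)

  # rows 2e apart have Row-IoU 0: both kept
  kept2 <- row_nms(list(mk(100, 0.9), mk(130, 0.8)), 0.5, 0.4, cfg,
                   n_points = 5, height = 320)
  expect_equal(length(kept2), 2)

  # suppression chain A~B, B~C, A!~C: A suppresses B, C survives
  kept3 <- row_nms(list(mk(100, 0.9), mk(103, 0.8), mk(106, 0.7)),
                   iou_threshold = 0.75, score_threshold = 0.4, cfg = cfg,
                   n_points = 5, height = 320)
  riou_ab <- (2 * 15 - 3) / (2 * 15 + 3)
  riou_ac <- (2 * 15 - 6) / (2 * 15 + 6)
  expect_gt(riou_ab, 0.75); expect_lt(riou_ac, 0.75)
  expect_equal(vapply(kept3, function(p) p$score, 0), c(0.9, 0.7))

  # score threshold filters up front
  kept4 <- row_nms(list(mk(100, 0.3)), 0.5, 0.4, cfg, n_points = 5, height = 320)
  expect_equal(length(kept4), 0)
})

test_that("dual-axis attention cost grows axis-wise inside the network", {
  # structural audit: the tape-side block multiplies H x H and W x W
  # attention matrices only, matching the module-level implementation
  H <- 5; W <- 9; C <- 4
  fmap <- array(rnorm(H * W * C), c(H, W, C))
  cfg <- dae_config(C, 2, C)
  pr <- init_dae_params(cfg, seed = 2)
  y <- dual_axis_attention(
    scatter_line_query(matrix(rnorm(3 * 2), 3, 2), cbind(1:3, 1:3), H, W),
    croprows:::fm_to_array(croprows:::fm_from_array(fmap) %*% pr$Wk_s, H, W),
    croprows:::fm_to_array(croprows:::fm_from_array(fmap) %*% pr$Wv_s, H, W))
  expect_equal(attr(y, "n_qk_dots"), H^2 + W^2)
  expect_lt(attr(y, "n_qk_dots"), (H * W)^2)
})
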
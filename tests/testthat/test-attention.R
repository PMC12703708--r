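test_that("scatter_line_query splats features with conserved mass", {
  feats <- matrix(c(1, 2, 3), 1, 3)
  m <- scatter_line_query(feats, cbind(2, 1), 4, 5)
  expect_equal(dim(m), c(4, 5, 3))
  expect_equal(m[2, 3, ], c(1, 2, 3))      # integer cell: no spread
  expect_equal(sum(m != 0), 3)

  m2 <- scatter_line_query(feats, cbind(2.5, 1.5), 4, 5)
  expect_equal(m2[2, 3, 1], 0.25)          # 4-way equal split
  expect_equal(m2[3, 4, 1], 0.25)
  expect_equal(apply(m2, 3, sum), c(1, 2, 3), tolerance = 1e-6)

  set.seed(1)
  feats3 <- matrix(rnorm(15), 5, 3)
  pos <- cbind(runif(5, 0, 4), runif(5, 0, 3))
  m3 <- scatter_line_query(feats3, pos, 4, 5)
  expect_equal(apply(m3, 3, sum), colSums(feats3), tolerance = 1e-6)

  empty <- scatter_line_query(matrix(0, 0, 3), matrix(0, 0, 2), 4, 5)
  expect_true(all(empty == 0))
})

test_that("axis_squeeze averages over the stated axis", {
  map <- array(c(1, 5, 3, 7), c(2, 2, 1))  # H=2, W=2
  expect_equal(as.vector(axis_squeeze(map, "horizontal")), c(2, 6))
  expect_equal(as.vector(axis_squeeze(map, "vertical")), c(3, 5))
  w1 <- array(c(4, 9), c(2, 1, 1))
  expect_equal(as.vector(axis_squeeze(w1, "horizontal")), c(4, 9))
})

test_that("dual-axis attention satisfies its algebraic contracts", {
  set.seed(2)
  # 1x1 map: output is twice the value vector
  q <- array(rnorm(4), c(1, 1, 4)); k <- array(rnorm(4), c(1, 1, 4))
  v <- array(rnorm(3), c(1, 1, 3))
  y <- dual_axis_attention(q, k, v)
  expect_equal(as.vector(y), 2 * as.vector(v), tolerance = 1e-9)

  # constant value map: convex combinations return the constant, doubled
  H <- 5; W <- 7
  qm <- array(rnorm(H * W * 4), c(H, W, 4)); km <- array(rnorm(H * W * 4), c(H, W, 4))
  cv <- c(0.3, -1.2)
  vm <- array(rep(cv, each = H * W), c(H, W, 2))
  y2 <- dual_axis_attention(qm, km, vm)
  for (c in 1:2) expect_equal(y2[, , c], matrix(2 * cv[c], H, W), tolerance = 1e-6)

  # attention matrices are exactly H x H and W x W; softmax rows sum to 1
  ad <- attr(y2, "attn_dims")
  expect_equal(ad$h, c(H, H)); expect_equal(ad$v, c(W, W))
  expect_equal(attr(y2, "n_qk_dots"), H^2 + W^2)
  expect_true(all(abs(attr(y2, "softmax_rowsums") - 1) <= 1e-6))

  # uniform logits with H=2, W=1: both rows get the mean of value rows
  q0 <- array(0, c(2, 1, 3)); k0 <- array(0, c(2, 1, 3))
  vv <- array(c(1, 3), c(2, 1, 1))
  y3 <- dual_axis_attention(q0, k0, vv)
  expect_equal(as.vector(y3), c(2 + 2, 2 + 2), tolerance = 1e-9)

  expect_error(dual_axis_attention(qm, km[, 1:3, , drop = FALSE], vm),
               class = "croprows_contract_violation")
})

test_that("full-attention reference agrees with dual-axis on 1x1 maps", {
  set.seed(3)
  q <- array(rnorm(4), c(1, 1, 4)); k <- array(rnorm(4), c(1, 1, 4))
  v <- array(rnorm(4), c(1, 1, 4))
  expect_equal(as.vector(full_attention_reference(q, k, v)),
               as.vector(dual_axis_attention(q, k, v)), tolerance = 1e-9)
  H <- 3; W <- 4
  yf <- full_attention_reference(array(rnorm(H * W * 2), c(H, W, 2)),
                                 array(rnorm(H * W * 2), c(H, W, 2)),
                                 array(rnorm(H * W * 2), c(H, W, 2)))
  expect_equal(attr(yf, "n_qk_dots"), (H * W)^2)
})

test_that("detail-enhancement gate squashes into (0,1) and is 0.5 at zero", {
  cfg <- dae_config(in_channels = 6, qk_channels = 4, v_channels = 6)
  pz <- init_dae_params(cfg, zero = TRUE)
  H <- 4; W <- 5
  g0 <- detail_enhancement_gate(matrix(0, 3, 6),
                                array(0, c(H, W, 4)), array(0, c(H, W, 6)),
                                cfg, pz)
  expect_equal(g0, array(0.5, c(H, W, 6)), tolerance = 1e-12)

  pr <- init_dae_params(cfg, seed = 5)
  g1 <- detail_enhancement_gate(matrix(rnorm(18), 3, 6),
                                array(rnorm(H * W * 4), c(H, W, 4)),
                                array(rnorm(H * W * 6), c(H, W, 6)), cfg, pr)
  expect_true(all(g1 > 0 & g1 < 1))
})

test_that("gate convolution is translation-equivariant away from borders", {
  set.seed(8)
  cfg <- dae_config(in_channels = 3, qk_channels = 2, v_channels = 3)
  pr <- init_dae_params(cfg, seed = 9)
  H <- 6; W <- 8
  km <- array(rnorm(H * W * 2), c(H, W, 2))
  vm <- array(rnorm(H * W * 3), c(H, W, 3))
  # zero margin columns so a one-cell shift permutes the convolution's
  # output columns exactly and the normalization statistics are unchanged
  km[, c(1, W - 1, W), ] <- 0; vm[, c(1, W - 1, W), ] <- 0
  # zero line features keep the broadcast query channel translation-neutral
  lf <- matrix(0, 4, 3)
  g <- detail_enhancement_gate(lf, km, vm, cfg, pr)
  shift <- function(a) { s <- a * 0; s[, 2:W, ] <- a[, 1:(W - 1), ]; s }
  gs <- detail_enhancement_gate(lf, shift(km), shift(vm), cfg, pr)
  expect_equal(gs[2:(H - 1), 3:(W - 1), ], g[2:(H - 1), 2:(W - 2), ],
               tolerance = 1e-6)
})

test_that("attention ROI align composes and respects the fusion identity", {
  set.seed(4)
  H <- 6; W <- 9; C <- 5; N <- 7
  cfg <- dae_config(in_channels = C, qk_channels = 3, v_channels = C)
  pr <- init_dae_params(cfg, seed = 11)
  fmap <- array(rnorm(H * W * C), c(H, W, C))
  pts <- cbind(runif(N, 0, W - 1), runif(N, 0, H - 1))

  out <- attention_roi_align(fmap, pts, cfg, pr)
  expect_equal(dim(out), c(N, C))

  # constant map + constant line feats: all outputs identical for interior
  # points (zero padding breaks spatial symmetry only at the borders)
  fc <- array(rep(seq_len(C), each = H * W), c(H, W, C))
  pts_in <- cbind(runif(N, 2, W - 3), runif(N, 2, H - 3))
  outc <- attention_roi_align(fc, pts_in, cfg, pr)
  expect_lt(max(apply(outc, 2, function(x) diff(range(x)))), 1e-8)

  # mode off bypasses to plain bilinear line features
  cfg_off <- dae_config(C, 3, C, mode = "off")
  off <- attention_roi_align(fmap, pts, cfg_off, pr)
  bc <- croprows:::bilinear_coeffs(pts, H, W)
  fm <- croprows:::fm_from_array(fmap)
  manual <- bc$wt[, 1] * fm[bc$ix[, 1], ]
  for (j in 2:4) manual <- manual + bc$wt[, j] * fm[bc$ix[, j], ]
  expect_equal(off, manual, tolerance = 1e-12)

  # widening v_channels never changes the axis-attention shapes
  y <- dual_axis_attention(array(rnorm(H * W * 3), c(H, W, 3)),
                           array(rnorm(H * W * 3), c(H, W, 3)),
                           array(rnorm(H * W * 10), c(H, W, 10)))
  expect_equal(attr(y, "attn_dims")$h, c(H, H))
  expect_equal(attr(y, "attn_dims")$v, c(W, W))
})
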
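# Cascaded anchor-line network: residual backbone, feature-pyramid fusion,
# line pooling along anchor lines, attention-guided ROI align, and three
# refinement stages (coarse anchors on the deepest map, refined anchors on
# progressively fused, higher-resolution maps).

#' Network/model configuration
#'
#' @param input_width,input_height network input resolution (px); both
#'   must be divisible by 32.
#' @param num_anchors number of anchor-line priors.
#' @param n_points number of sample scanlines N per row.
#' @param width_mult channel width multiplier on the residual backbone.
#' @param attention_mode "dae", "full" or "off".
#' @param fpn_enabled enable top-down feature-pyramid fusion.
#' @param hidden_units width of the two shared head layers.
#' @param stem_kernel stem convolution kernel size (7 for the standard
#'   backbone; the tiny profile uses 3 to cut im2col cost).
#' @return an object of class `model_config`.
#' @export
model_config <- function(input_width = 800, input_height = 320,
                         num_anchors = 64, n_points = 40,
                         width_mult = 1, attention_mode = c("dae", "full", "off"),
                         fpn_enabled = TRUE, hidden_units = NULL,
                         stem_kernel = 7L) {
  stopifnot(input_width %% 32 == 0, input_height %% 32 == 0,
            num_anchors >= 1, n_points >= 2, width_mult > 0)
  ch <- pmax(4L, as.integer(round(c(64, 64, 128, 256, 512) * width_mult)))
  fpn_ch <- max(8L, as.integer(round(128 * width_mult)))
  if (is.null(hidden_units)) hidden_units <- max(32L, as.integer(round(1024 * width_mult)))
  structure(list(input_width = input_width, input_height = input_height,
                 num_anchors = num_anchors, n_points = n_points,
                 width_mult = width_mult, channels = ch, fpn_channels = fpn_ch,
                 attention_mode = match.arg(attention_mode),
                 fpn_enabled = fpn_enabled, hidden_units = hidden_units,
                 stem_kernel = as.integer(stem_kernel)),
            class = "model_config")
}

#' Initialize the learnable anchor-line priors
#'
#' Start points are spread uniformly along the bottom border (70%) and the
#' lower halves of the two side borders; angles are drawn uniformly from
#' (15, 165) degrees; lengths start at N (full rows). Deterministic for a
#' given seed.
#'
#' @param num_anchors number of anchors.
#' @param n_points N sample scanlines.
#' @param seed integer RNG seed.
#' @param width,height network input resolution (px).
#' @return num_anchors x 4 matrix with columns start_x, start_y, theta,
#'   length; every row satisfies the anchor-line invariants.
#' @export
init_anchor_priors <- function(num_anchors, n_points, seed = 0L,
                               width = 800, height = 320) {
  stopifnot(num_anchors >= 1)
  with_seed(seed, {
    n_bottom <- max(1L, as.integer(round(0.7 * num_anchors)))
    n_side <- num_anchors - n_bottom
    n_left <- n_side %/% 2L
    n_right <- n_side - n_left
    sx <- c(width * (seq_len(n_bottom) - 0.5) / n_bottom,
            rep(0, n_left), rep(width, n_right))
    sy <- c(rep(height, n_bottom),
            height * (1 - 0.5 * (seq_len(n_left) - 0.5) / max(1, n_left)),
            height * (1 - 0.5 * (seq_len(n_right) - 0.5) / max(1, n_right)))
    theta <- stats::runif(num_anchors, 15, 165) * pi / 180
    cbind(start_x = sx, start_y = sy, theta = theta,
          length = rep(n_points, num_anchors))
  })
}

# He-initialized conv / linear parameter helpers
p_conv <- function(cin, cout, k, seed_env) {
  param_new(matrix(stats::rnorm(cin * k * k * cout, sd = sqrt(2 / (cin * k * k))),
                   cin * k * k, cout))
}
p_lin <- function(cin, cout, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / cin)
  param_new(matrix(stats::rnorm(cin * cout, sd = sd), cin, cout))
}
p_norm <- function(c) list(g = param_new(matrix(1, 1, c)),
                           b = param_new(matrix(0, 1, c)))

#' Build an anchor-line row-detection network
#'
#' @param cfg a [model_config()].
#' @param seed integer seed controlling weight initialization and anchor
#'   priors.
#' @return an object of class `row_network` holding all parameter stores.
#' @export
build_network <- function(cfg, seed = 0L) {
  ch <- cfg$channels; Fc <- cfg$fpn_channels
  net <- with_seed(seed, {
    blocks <- function(cin, cout) list(
      c1 = p_conv(cin, cout, 3), n1 = p_norm(cout),
      c2 = p_conv(cout, cout, 3), n2 = p_norm(cout),
      sk = if (cin != cout) p_conv(cin, cout, 1) else NULL,
      skn = if (cin != cout) p_norm(cout) else NULL)
    mk_head <- function() {
      hid <- cfg$hidden_units
      list(fc1 = p_lin(cfg$n_points * Fc, hid), b1 = param_new(matrix(0, 1, hid)),
           fc2 = p_lin(hid, hid), b2 = param_new(matrix(0, 1, hid)),
           score = p_lin(hid, 1, sd = 0.01), score_b = param_new(matrix(-2, 1, 1)),
           delta = p_lin(hid, 4, sd = 0.01), delta_b = param_new(matrix(0, 1, 4)),
           offs = p_lin(hid, cfg$n_points, sd = 0.01),
           offs_b = param_new(matrix(0, 1, cfg$n_points)))
    }
    mk_attn <- function() {
      Cqk <- max(4L, Fc %/% 2L); Cmid <- 2L * Cqk + Fc
      list(Cqk = Cqk, Cmid = Cmid,
           q_s = p_lin(Fc, Cqk), k_s = p_lin(Fc, Cqk), v_s = p_lin(Fc, Fc),
           q_e = p_lin(Fc, Cqk), k_e = p_lin(Fc, Cqk), v_e = p_lin(Fc, Fc),
           gate_conv = p_conv(Cmid, Cmid, 3), gate_conv_b = param_new(matrix(0, 1, Cmid)),
           gate_norm = p_norm(Cmid),
           gate_proj = p_lin(Cmid, Fc), gate_proj_b = param_new(matrix(0, 1, Fc)))
    }
    list(
      stem = p_conv(3, ch[1], cfg$stem_kernel), stem_n = p_norm(ch[1]),
      l1 = list(blocks(ch[1], ch[2]), blocks(ch[2], ch[2])),
      l2 = list(blocks(ch[2], ch[3]), blocks(ch[3], ch[3])),
      l3 = list(blocks(ch[3], ch[4]), blocks(ch[4], ch[4])),
      l4 = list(blocks(ch[4], ch[5]), blocks(ch[5], ch[5])),
      lat1 = p_conv(ch[3], Fc, 1), lat1_n = p_norm(Fc),
      lat2 = p_conv(ch[4], Fc, 1), lat2_n = p_norm(Fc),
      lat3 = p_conv(ch[5], Fc, 1), lat3_n = p_norm(Fc),
      sm1 = p_conv(Fc, Fc, 3), sm1_n = p_norm(Fc),
      sm2 = p_conv(Fc, Fc, 3), sm2_n = p_norm(Fc),
      sm3 = p_conv(Fc, Fc, 3), sm3_n = p_norm(Fc),
      pool1d = lapply(1:3, function(i) list(w = p_conv(Fc, Fc, 1) , b = NULL)),
      heads = lapply(1:3, function(i) mk_head()),
      attn = lapply(1:3, function(i) mk_attn()),
      priors = param_new(init_anchor_priors(cfg$num_anchors, cfg$n_points,
                                            seed = seed + 1L,
                                            width = cfg$input_width,
                                            height = cfg$input_height)))
  })
  # the along-line 1D convolution uses a length-3 kernel
  net$pool1d <- with_seed(seed + 2L, lapply(1:3, function(i)
    list(w = param_new(matrix(stats::rnorm(Fc * 3 * Fc, sd = sqrt(2 / (Fc * 3))), Fc * 3, Fc)),
         b = param_new(matrix(0, 1, Fc)))))
  structure(list(params = net, cfg = cfg), class = "row_network")
}

# flat list of all parameter stores in a network
network_params <- function(net) {
  out <- list()
  walk <- function(x) {
    if (inherits(x, "croprows_param")) out[[length(out) + 1]] <<- x
    else if (is.list(x)) for (e in x) if (!is.null(e)) walk(e)
  }
  walk(net$params)
  out
}

#' Count trainable parameters of a network
#' @param net a `row_network`.
#' @return integer total parameter count.
#' @export
count_parameters <- function(net)
  sum(vapply(network_params(net), function(p) length(p$val), 0))

# ---- tape-side building blocks -----------------------------------------

conv_norm_relu <- function(tp, x, w, nrm, B, H, W, k, stride, grp_out) {
  y <- op_conv2d(tp, x, leaf(tp, w), NULL, B, H, W, k, stride)
  y <- op_instnorm(tp, y, leaf(tp, nrm$g), leaf(tp, nrm$b), grp_out)
  op_relu(tp, y)
}

res_block <- function(tp, x, blk, B, H, W, stride) {
  OH <- H %/% stride; OW <- W %/% stride
  grp <- rep(seq_len(B), each = OH * OW)
  y <- conv_norm_relu(tp, x, blk$c1, blk$n1, B, H, W, 3, stride, grp)
  y <- op_conv2d(tp, y, leaf(tp, blk$c2), NULL, B, OH, OW, 3, 1)
  y <- op_instnorm(tp, y, leaf(tp, blk$n2$g), leaf(tp, blk$n2$b), grp)
  sk <- if (!is.null(blk$sk)) {
    s <- op_conv2d(tp, x, leaf(tp, blk$sk), NULL, B, H, W, 1, stride)
    op_instnorm(tp, s, leaf(tp, blk$skn$g), leaf(tp, blk$skn$b), grp)
  } else x
  op_relu(tp, op_add(tp, y, sk))
}

res_layer <- function(tp, x, blks, B, H, W, stride) {
  y <- res_block(tp, x, blks[[1]], B, H, W, stride)
  res_block(tp, y, blks[[2]], B, H %/% stride, W %/% stride, 1)
}

# backbone + pyramid; x is (B*H*W) x 3
backbone_pyramid <- function(net, tp, x, B) {
  cfg <- net$cfg; pr <- net$params
  H <- cfg$input_height; W <- cfg$input_width
  g <- function(h, w) rep(seq_len(B), each = h * w)
  y <- conv_norm_relu(tp, x, pr$stem, pr$stem_n, B, H, W, cfg$stem_kernel, 2,
                      g(H / 2, W / 2))
  y <- op_maxpool2(tp, y, B, H %/% 2, W %/% 2)
  h4 <- H %/% 4; w4 <- W %/% 4
  c1 <- res_layer(tp, y, pr$l1, B, h4, w4, 1)                 # stride 4
  c2 <- res_layer(tp, c1, pr$l2, B, h4, w4, 2)                # stride 8
  c3 <- res_layer(tp, c2, pr$l3, B, h4 %/% 2, w4 %/% 2, 2)    # stride 16
  c4 <- res_layer(tp, c3, pr$l4, B, h4 %/% 4, w4 %/% 4, 2)    # stride 32
  d2 <- c(h4 %/% 2, w4 %/% 2); d3 <- c(h4 %/% 4, w4 %/% 4); d4 <- c(h4 %/% 8, w4 %/% 8)
  lat <- function(x, w, nrm, dd) {
    y <- op_conv2d(tp, x, leaf(tp, w), NULL, B, dd[1], dd[2], 1, 1)
    op_instnorm(tp, y, leaf(tp, nrm$g), leaf(tp, nrm$b), g(dd[1], dd[2]))
  }
  p3 <- lat(c4, pr$lat3, pr$lat3_n, d4)
  p2 <- lat(c3, pr$lat2, pr$lat2_n, d3)
  p1 <- lat(c2, pr$lat1, pr$lat1_n, d2)
  if (cfg$fpn_enabled) {
    p2 <- op_add(tp, p2, op_upsample_nn(tp, p3, B, d4[1], d4[2], d3[1], d3[2]))
    p1 <- op_add(tp, p1, op_upsample_nn(tp, p2, B, d3[1], d3[2], d2[1], d2[2]))
  }
  sm <- function(x, w, nrm, dd)
    conv_norm_relu(tp, x, w, nrm, B, dd[1], dd[2], 3, 1, g(dd[1], dd[2]))
  list(maps = list(sm(p1, pr$sm1, pr$sm1_n, d2),
                   sm(p2, pr$sm2, pr$sm2_n, d3),
                   sm(p3, pr$sm3, pr$sm3_n, d4)),
       dims = list(d2, d3, d4),
       strides = c(8L, 16L, 32L))
}

# reference abscissae of anchors (A x 4 value matrix) at scanlines ys
anchor_ref_xs <- function(anchors, ys) {
  A <- nrow(anchors)
  cot <- 1 / tan(clamp(anchors[, 3], 0.06, pi - 0.06))
  matrix(anchors[, 1], A, length(ys)) +
    (matrix(anchors[, 2], A, length(ys)) -
       matrix(ys, A, length(ys), byrow = TRUE)) * cot
}

# (S*N x F) -> (S x N*F), sequence-major flatten
op_seq_flatten <- function(tape, x, N) {
  x <- as_node(tape, x)
  F <- ncol(x$val); S <- nrow(x$val) %/% N
  fwd <- function(v) { y <- t(v); dim(y) <- c(F * N, S); t(y) }
  bwd <- function(g) { y <- t(g); dim(y) <- c(F, N * S); t(y) }
  node_new(tape, fwd(x$val), list(x), function(nd) list(bwd(nd$grad)), x$track)
}

# attention-guided ROI align on the tape, one image
attn_block_tape <- function(tp, att, map_b, pooled_b, ix, wt, Hf, Wf, mode) {
  if (mode == "off") return(pooled_b)
  q_line <- op_matmul(tp, pooled_b, leaf(tp, att$q_s))
  n_pix <- Hf * Wf
  qmap <- op_scatter_bilinear(tp, q_line, ix, wt, n_pix)
  kmap <- op_matmul(tp, map_b, leaf(tp, att$k_s))
  vmap <- op_matmul(tp, map_b, leaf(tp, att$v_s))
  grp_y <- rep(seq_len(Hf), each = Wf)
  grp_x <- rep(seq_len(Wf), times = Hf)
  if (mode == "full") {
    A <- op_softmax_rows(tp, op_matmul_nt(tp, qmap, kmap))
    y <- op_scale(tp, op_matmul(tp, A, vmap), 2)
  } else {
    qh <- op_groupmean(tp, qmap, grp_y, Hf); kh <- op_groupmean(tp, kmap, grp_y, Hf)
    vh <- op_groupmean(tp, vmap, grp_y, Hf)
    qv <- op_groupmean(tp, qmap, grp_x, Wf); kv <- op_groupmean(tp, kmap, grp_x, Wf)
    vv <- op_groupmean(tp, vmap, grp_x, Wf)
    oh <- op_matmul(tp, op_softmax_rows(tp, op_matmul_nt(tp, qh, kh)), vh)
    ov <- op_matmul(tp, op_softmax_rows(tp, op_matmul_nt(tp, qv, kv)), vv)
    y <- op_add(tp, op_rows_select(tp, oh, grp_y), op_rows_select(tp, ov, grp_x))
  }
  # detail-enhancement gate
  q1 <- op_matmul(tp, op_groupmean(tp, pooled_b, rep(1L, nrow(pooled_b$val)), 1L),
                  leaf(tp, att$q_e))
  qb <- op_rows_select(tp, q1, rep(1L, n_pix))
  k1 <- op_matmul(tp, map_b, leaf(tp, att$k_e))
  v1 <- op_matmul(tp, map_b, leaf(tp, att$v_e))
  h <- op_concat_cols(tp, list(qb, k1, v1))
  h <- op_conv2d(tp, h, leaf(tp, att$gate_conv), leaf(tp, att$gate_conv_b),
                 1L, Hf, Wf, 3, 1)
  h <- op_instnorm(tp, h, leaf(tp, att$gate_norm$g), leaf(tp, att$gate_norm$b),
                   rep(1L, n_pix))
  h <- op_relu(tp, h)
  gate <- op_sigmoid(tp, op_bias(tp, op_matmul(tp, h, leaf(tp, att$gate_proj)),
                                 leaf(tp, att$gate_proj_b)))
  fused <- op_add(tp, op_mul(tp, gate, y), y)
  enriched <- op_gather_bilinear(tp, fused, ix, wt)
  op_add(tp, pooled_b, enriched)
}

# Full cascade forward on a tape. x: (B*H*W) x 3 input features.
# Returns per-stage nodes plus realized (numeric) anchors per stage.
net_forward <- function(net, tp, x, B) {
  cfg <- net$cfg; pr <- net$params
  A <- cfg$num_anchors; N <- cfg$n_points; Fc <- cfg$fpn_channels
  ys <- sample_ys(N, cfg$input_height)
  pyr <- backbone_pyramid(net, tp, x, B)
  # stage order: deepest map first
  stage_maps <- list(pyr$maps[[3]], pyr$maps[[2]], pyr$maps[[1]])
  stage_dims <- list(pyr$dims[[3]], pyr$dims[[2]], pyr$dims[[1]])
  stage_strides <- c(pyr$strides[3], pyr$strides[2], pyr$strides[1])

  prior_leaf <- leaf(tp, pr$priors)
  base_node <- op_rows_select(tp, prior_leaf, rep(seq_len(A), B))  # (B*A) x 4
  base_val <- base_node$val
  stages <- vector("list", 3)
  d_scale <- c(0.1 * cfg$input_width, 0.1 * cfg$input_height, 0.3, 0.3 * N)
  o_scale <- 0.1 * cfg$input_width

  for (s in 1:3) {
    dd <- stage_dims[[s]]; Hf <- dd[1]; Wf <- dd[2]; stride <- stage_strides[s]
    n_pix <- Hf * Wf
    # pooling positions from current anchors (values, detached)
    ix_all <- matrix(0L, B * A * N, 4); wt_all <- matrix(0, B * A * N, 4)
    for (b in seq_len(B)) {
      anc <- base_val[(b - 1) * A + seq_len(A), , drop = FALSE]
      xr <- anchor_ref_xs(anc, ys)                       # A x N
      px <- as.vector(t(xr)) / stride - 0.5
      py <- rep(ys, A) / stride - 0.5
      bc <- bilinear_coeffs(cbind(px, py), Hf, Wf, warn = FALSE)
      rows <- (b - 1) * A * N + seq_len(A * N)
      ix_all[rows, ] <- bc$ix + (b - 1L) * n_pix
      wt_all[rows, ] <- bc$wt
    }
    feat <- op_gather_bilinear(tp, stage_maps[[s]], ix_all, wt_all)  # (B*A*N) x F
    pooled <- op_relu(tp, op_conv1d(tp, feat, leaf(tp, pr$pool1d[[s]]$w),
                                    leaf(tp, pr$pool1d[[s]]$b), B * A, N))
    if (cfg$attention_mode != "off") {
      per_img <- vector("list", B)
      for (b in seq_len(B)) {
        rows <- (b - 1) * A * N + seq_len(A * N)
        map_rows <- (b - 1) * n_pix + seq_len(n_pix)
        per_img[[b]] <- attn_block_tape(
          tp, pr$attn[[s]],
          op_rows_select(tp, stage_maps[[s]], map_rows),
          op_rows_select(tp, pooled, rows),
          ix_all[rows, , drop = FALSE] - (b - 1L) * n_pix,
          wt_all[rows, , drop = FALSE], Hf, Wf, cfg$attention_mode)
      }
      pooled <- op_rbind(tp, per_img)
    }
    flat <- op_seq_flatten(tp, pooled, N)                 # (B*A) x N*F
    hd <- pr$heads[[s]]
    h <- op_relu(tp, op_bias(tp, op_matmul(tp, flat, leaf(tp, hd$fc1)), leaf(tp, hd$b1)))
    h <- op_relu(tp, op_bias(tp, op_matmul(tp, h, leaf(tp, hd$fc2)), leaf(tp, hd$b2)))
    score <- op_bias(tp, op_matmul(tp, h, leaf(tp, hd$score)), leaf(tp, hd$score_b))
    drw <- op_bias(tp, op_matmul(tp, h, leaf(tp, hd$delta)), leaf(tp, hd$delta_b))
    deltas <- op_mul(tp, drw, matrix(d_scale, B * A, 4, byrow = TRUE))
    offs <- op_scale(tp, op_bias(tp, op_matmul(tp, h, leaf(tp, hd$offs)),
                                 leaf(tp, hd$offs_b)), o_scale)
    anchors_pred <- op_add(tp, base_node, deltas)         # in-graph anchor params
    stages[[s]] <- list(score = score, deltas = deltas, offsets = offs,
                        anchors_pred = anchors_pred, base_val = base_val)
    # next stage pools along refined anchors (values detached; geometry clamped)
    nb <- base_val + deltas$val
    nb[, 2] <- clamp(nb[, 2], 0.25 * cfg$input_height, cfg$input_height)
    nb[, 3] <- clamp(nb[, 3], 0.06, pi - 0.06)
    nb[, 4] <- clamp(nb[, 4], 2, N)
    base_node <- op_add(tp, base_node, deltas)
    base_val <- nb
  }
  list(stages = stages, ys = ys)
}

# realized numeric predictions from the final stage for one image
realize_predictions <- function(net, fw, b) {
  cfg <- net$cfg; A <- cfg$num_anchors; N <- cfg$n_points
  st <- fw$stages[[3]]
  rows <- (b - 1) * A + seq_len(A)
  anc <- st$base_val[rows, , drop = FALSE] * 0 + (st$anchors_pred$val[rows, , drop = FALSE])
  anc[, 3] <- clamp(anc[, 3], 0.06, pi - 0.06)
  offs <- st$offsets$val[rows, , drop = FALSE]
  scores <- 1 / (1 + exp(-st$score$val[rows, 1]))
  lapply(seq_len(A), function(a) {
    al <- anchor_line(anc[a, 1], clamp(anc[a, 2], 1, cfg$input_height),
                      anc[a, 3], clamp(anc[a, 4], 1, N))
    row_prediction(scores[a], al, offs[a, ])
  })
}

#' Single-image cascade forward pass
#'
#' Runs the full three-stage cascade on one image and returns the
#' per-stage outputs (scores, parameter deltas, per-scanline offsets, and
#' the refined anchor sets p1 and p2) plus the realized final
#' predictions. Deterministic: repeated calls give identical output.
#'
#' @param net a `row_network` from [build_network()].
#' @param image H x W x 3 numeric array in [0, 1] at the network input
#'   resolution.
#' @return list with `stages` (per stage: scores, deltas, offsets),
#'   `anchor_sets` (p0, p1, p2 matrices), and `predictions`
#'   (list of [row_prediction()]).
#' @export
cascade_forward <- function(net, image) {
  cfg <- net$cfg
  stopifnot(dim(image)[1] == cfg$input_height, dim(image)[2] == cfg$input_width)
  x <- fm_from_array(image)
  tp <- tape_new()
  fw <- net_forward(net, tp, x, 1L)
  A <- cfg$num_anchors
  sets <- list(p0 = net$params$priors$val)
  sets$p1 <- sets$p0 + fw$stages[[1]]$deltas$val
  sets$p2 <- sets$p1 + fw$stages[[2]]$deltas$val
  stages <- lapply(fw$stages, function(st)
    list(scores = 1 / (1 + exp(-st$score$val[, 1])),
         deltas = st$deltas$val, offsets = st$offsets$val))
  list(stages = stages, anchor_sets = sets,
       predictions = realize_predictions(net, fw, 1L))
}

#' Line pooling: bilinear samples along anchor points plus an along-line
#' 1D convolution
#'
#' @param fmap H x W x C feature map array.
#' @param points N x 2 matrix of (x, y) sample positions in feature px.
#' @param kernel optional (C*3) x Cout 1D convolution kernel (channel-major
#'   rows); `NULL` applies no mixing (identity pooling).
#' @param bias optional 1 x Cout bias.
#' @return N x Cout matrix of pooled features.
#' @export
line_pool <- function(fmap, points, kernel = NULL, bias = NULL) {
  d <- dim(fmap)
  fm <- fm_from_array(fmap)
  bc <- bilinear_coeffs(as.matrix(points), d[1], d[2])
  out <- bc$wt[, 1] * fm[bc$ix[, 1], , drop = FALSE]
  for (j in 2:4) out <- out + bc$wt[, j] * fm[bc$ix[, j], , drop = FALSE]
  if (is.null(kernel)) return(out)
  tp <- tape_new()
  nd <- op_conv1d(tp, out, kernel, bias, 1L, nrow(out))
  nd$val
}

#' Greedy line non-maximum suppression
#'
#' Predictions below `score_threshold` are dropped; the remainder are
#' processed by decreasing score, suppressing any prediction whose
#' Row-IoU with an already kept one exceeds `iou_threshold`.
#'
#' @param preds list of [row_prediction()].
#' @param iou_threshold Row-IoU suppression threshold.
#' @param score_threshold minimum score kept.
#' @param cfg a [riou_config()].
#' @param n_points,height discretization used for Row-IoU.
#' @return filtered list of [row_prediction()], by decreasing score.
#' @export
row_nms <- function(preds, iou_threshold = 0.5, score_threshold = 0.4,
                    cfg = riou_config(), n_points = NULL, height = NULL) {
  scores <- vapply(preds, function(p) p$score, 0)
  keep_idx <- which(scores >= score_threshold)
  if (length(keep_idx) == 0) return(list())
  if (is.null(n_points)) n_points <- length(preds[[keep_idx[1]]]$offsets)
  if (is.null(height)) height <- 320
  rows <- lapply(keep_idx, function(i)
    anchor_to_points(preds[[i]]$anchor, preds[[i]]$offsets, n_points, height))
  ord <- keep_idx[order(scores[keep_idx], decreasing = TRUE)]
  rows <- rows[order(scores[keep_idx], decreasing = TRUE)]
  kept <- integer(0); kept_rows <- list()
  for (i in seq_along(ord)) {
    ok <- TRUE
    for (kr in kept_rows) {
      if (row_iou(rows[[i]], kr, cfg) > iou_threshold) { ok <- FALSE; break }
    }
    if (ok) { kept <- c(kept, ord[i]); kept_rows[[length(kept_rows) + 1]] <- rows[[i]] }
  }
  preds[kept]
}
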
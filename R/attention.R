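# Attention-guided ROI align: dual-axis squeeze attention plus a
# convolutional detail-enhancement gate, producing context-enriched
# features along each anchor line. Feature maps are H x W x C arrays
# (origin top-left); the axis squeeze averages the query/key/value maps
# over one spatial axis so attention matrices are H x H and W x W only.

#' Dual-axis attention configuration
#'
#' @param in_channels feature channels C of the input map.
#' @param qk_channels query/key projection width.
#' @param v_channels value projection width; the fused ROI-align path
#'   requires v_channels == in_channels.
#' @param gate_activation activation of the enhancement branch ("relu").
#' @param mode "dae" (dual-axis), "full" (reference full attention), or
#'   "off" (bypass; plain pooled features).
#' @return an object of class `dae_config`.
#' @export
dae_config <- function(in_channels, qk_channels = max(4L, in_channels %/% 2L),
                       v_channels = in_channels, gate_activation = "relu",
                       mode = c("dae", "full", "off")) {
  stopifnot(in_channels > 0, qk_channels > 0, v_channels > 0,
            v_channels <= 512)
  structure(list(in_channels = in_channels, qk_channels = qk_channels,
                 v_channels = v_channels, gate_activation = gate_activation,
                 mode = match.arg(mode)), class = "dae_config")
}

#' Initialize the projection and gate weights of the attention block
#'
#' @param cfg a [dae_config()].
#' @param seed RNG seed; `NULL` keeps the current RNG state.
#' @param zero if TRUE all weights start at zero (useful for contract
#'   tests; the gate then outputs 0.5 everywhere).
#' @return named list of weight matrices (inputs multiply on the left,
#'   x %*% W); convolution kernels use the channel-major row layout of
#'   the conv ops.
#' @export
init_dae_params <- function(cfg, seed = NULL, zero = FALSE) {
  C <- cfg$in_channels; Cqk <- cfg$qk_channels; Cv <- cfg$v_channels
  Cmid <- 2L * Cqk + Cv
  mk <- function(nr, nc) {
    if (zero) matrix(0, nr, nc)
    else matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
  }
  build <- function() list(
    Wq_s = mk(C, Cqk), Wk_s = mk(C, Cqk), Wv_s = mk(C, Cv),
    Wq_e = mk(C, Cqk), Wk_e = mk(C, Cqk), Wv_e = mk(C, Cv),
    conv_gate = mk(Cmid * 9L, Cmid), conv_gate_b = matrix(0, 1, Cmid),
    norm_gamma = matrix(1, 1, Cmid), norm_beta = matrix(0, 1, Cmid),
    proj_gate = mk(Cmid, C), proj_gate_b = matrix(0, 1, C))
  if (is.null(seed)) build() else with_seed(seed, build())
}

# bilinear interpolation coefficients of positions (x, y) on an H x W grid
# with cells at integer coordinates (0-based); returns y-major row indices
# and weights, border-clamped (with a warning if out of bounds)
bilinear_coeffs <- function(positions, H, W, warn = TRUE) {
  x <- positions[, 1]; y <- positions[, 2]
  oob <- x < 0 | x > W - 1 | y < 0 | y > H - 1
  if (any(oob) && warn)
    warning(sprintf("%d anchor position(s) outside the feature map; clamped", sum(oob)))
  x <- clamp(x, 0, W - 1); y <- clamp(y, 0, H - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, W - 1); y1 <- pmin(y0 + 1, H - 1)
  wx <- x - x0; wy <- y - y0
  ix <- cbind(y0 * W + x0, y0 * W + x1, y1 * W + x0, y1 * W + x1) + 1
  wt <- cbind((1 - wy) * (1 - wx), (1 - wy) * wx, wy * (1 - wx), wy * wx)
  list(ix = matrix(as.integer(ix), ncol = 4), wt = wt)
}

fm_from_array <- function(arr) {
  d <- dim(arr)                      # H x W x C
  m <- matrix(aperm(arr, c(2, 1, 3)), d[1] * d[2], d[3])  # y-major rows
  attr(m, "hw") <- d[1:2]
  m
}

fm_to_array <- function(m, H, W) {
  aperm(array(m, c(W, H, ncol(m))), c(2, 1, 3))
}

#' Splat per-point anchor-line features onto a zero spatial map
#'
#' Each of the N line features is bilinearly scattered at its anchor
#' sample position, conserving total mass; this realizes the reshape of
#' line-extracted queries onto the (C, H, W) spatial layout that the axis
#' squeeze consumes.
#'
#' @param line_feats N x C matrix of per-point features.
#' @param positions N x 2 matrix of (x, y) positions in feature-map px.
#' @param out_h,out_w output map size.
#' @return H x W x C array.
#' @export
scatter_line_query <- function(line_feats, positions, out_h, out_w) {
  C <- ncol(line_feats)
  if (nrow(line_feats) == 0) return(array(0, c(out_h, out_w, C)))
  bc <- bilinear_coeffs(as.matrix(positions), out_h, out_w)
  m <- matrix(0, out_h * out_w, C)
  for (j in 1:4) {
    rs <- rowsum(line_feats * bc$wt[, j], bc$ix[, j])
    ui <- as.integer(rownames(rs))
    m[ui, ] <- m[ui, ] + rs
  }
  fm_to_array(m, out_h, out_w)
}

#' Average a feature map over one spatial axis
#'
#' @param map H x W x C array.
#' @param axis "horizontal" (average over W, giving H x C) or "vertical"
#'   (average over H, giving W x C).
#' @return matrix of squeezed features.
#' @export
axis_squeeze <- function(map, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  d <- dim(map)
  if (axis == "horizontal") {
    out <- apply(map, c(1, 3), mean)        # H x C
  } else {
    out <- apply(map, c(2, 3), mean)        # W x C
  }
  matrix(out, ncol = d[3])
}

#' Dual-axis squeeze attention
#'
#' Queries, keys and values are squeezed along each spatial axis; softmax
#' attention runs over the H height positions and the W width positions
#' separately, and the per-position output is the sum of the two axis
#' readouts: y(i,j) = sum_p softmax_p(qh_i . kh_p) vh_p +
#' sum_p softmax_p(qv_j . kv_p) vv_p. Attention matrices are exactly
#' H x H and W x W (attached as attribute `attn_dims`).
#'
#' @param qmap,kmap H x W x Cqk projected query/key maps.
#' @param vmap H x W x Cv projected value map.
#' @return H x W x Cv array with attributes `attn_dims` and `n_qk_dots`.
#' @export
dual_axis_attention <- function(qmap, kmap, vmap) {
  dq <- dim(qmap)
  if (!identical(dim(kmap)[1:2], dq[1:2]) || !identical(dim(vmap)[1:2], dq[1:2]) ||
      !identical(dim(kmap)[3], dq[3]))
    cr_stop("attention map shapes are inconsistent", "croprows_contract_violation")
  H <- dq[1]; W <- dq[2]; Cv <- dim(vmap)[3]
  qh <- axis_squeeze(qmap, "horizontal"); kh <- axis_squeeze(kmap, "horizontal")
  vh <- axis_squeeze(vmap, "horizontal")
  qv <- axis_squeeze(qmap, "vertical");  kv <- axis_squeeze(kmap, "vertical")
  vv <- axis_squeeze(vmap, "vertical")
  softmax_rows <- function(z) { z <- z - apply(z, 1, max); e <- exp(z); e / rowSums(e) }
  Ah <- softmax_rows(tcrossprod(qh, kh))    # H x H
  Av <- softmax_rows(tcrossprod(qv, kv))    # W x W
  oh <- Ah %*% vh                           # H x Cv
  ov <- Av %*% vv                           # W x Cv
  out <- array(0, c(H, W, Cv))
  for (c in seq_len(Cv))
    out[, , c] <- outer(oh[, c], rep(1, W)) + outer(rep(1, H), ov[, c])
  attr(out, "attn_dims") <- list(h = dim(Ah), v = dim(Av))
  attr(out, "n_qk_dots") <- H^2 + W^2
  attr(out, "softmax_rowsums") <- c(rowSums(Ah), rowSums(Av))
  out
}

#' Full (non-squeezed) attention reference
#'
#' Plain softmax attention over all H*W positions; used as the structural
#' ablation reference. On 1 x 1 maps it agrees exactly with
#' [dual_axis_attention()] up to the factor-2 sum of the two axis terms.
#'
#' @inheritParams dual_axis_attention
#' @return H x W x Cv array with attributes `attn_dims` and `n_qk_dots`.
#' @export
full_attention_reference <- function(qmap, kmap, vmap) {
  d <- dim(qmap); H <- d[1]; W <- d[2]
  q <- fm_from_array(qmap); k <- fm_from_array(kmap); v <- fm_from_array(vmap)
  z <- tcrossprod(q, k)
  z <- z - apply(z, 1, max); e <- exp(z); A <- e / rowSums(e)
  out <- fm_to_array(2 * (A %*% v), H, W)   # doubled to match the two-axis sum
  attr(out, "attn_dims") <- list(full = dim(A))
  attr(out, "n_qk_dots") <- (H * W)^2
  out
}

#' Convolutional detail-enhancement gate
#'
#' A query summarizing the anchor line (projected mean line feature,
#' broadcast spatially) is concatenated with dense key/value maps, passed
#' through a 3x3 convolution, channel normalization and activation, then
#' linearly projected back to C channels and squashed to (0, 1).
#'
#' @param line_feats N x C matrix of raw anchor-line features.
#' @param kmap H x W x Cqk dense key map of the enhancement branch.
#' @param vmap H x W x Cv dense value map of the enhancement branch.
#' @param cfg a [dae_config()].
#' @param params weights from [init_dae_params()].
#' @return H x W x C gate array with entries in (0, 1).
#' @export
detail_enhancement_gate <- function(line_feats, kmap, vmap, cfg, params) {
  H <- dim(kmap)[1]; W <- dim(kmap)[2]
  q1 <- if (nrow(line_feats) > 0) colMeans(line_feats) else numeric(cfg$in_channels)
  q1 <- matrix(q1, 1) %*% params$Wq_e                 # 1 x Cqk
  qb <- matrix(rep(q1, each = H * W), H * W)          # broadcast over space
  km <- fm_from_array(kmap); vm <- fm_from_array(vmap)
  x <- cbind(qb, km, vm)                              # (HW) x (2Cqk + Cv)
  ci <- conv_indices(1L, H, W, 3L, 1L, 1L)
  Xp <- rbind(x, 0)
  cols <- Xp[ci$Gv, , drop = FALSE]
  dim(cols) <- c(H * W, 9L * ncol(x))
  h <- sweep(cols %*% params$conv_gate, 2, as.vector(params$conv_gate_b), "+")
  # channel normalization + affine
  mu <- colMeans(h); sd <- sqrt(colMeans(sweep(h, 2, mu)^2) + 1e-5)
  h <- sweep(sweep(h, 2, mu), 2, sd, "/")
  h <- sweep(sweep(h, 2, as.vector(params$norm_gamma), "*"), 2,
             as.vector(params$norm_beta), "+")
  if (cfg$gate_activation == "relu") h[h < 0] <- 0
  g <- sweep(h %*% params$proj_gate, 2, as.vector(params$proj_gate_b), "+")
  fm_to_array(1 / (1 + exp(-g)), H, W)
}

#' Attention-guided ROI align
#'
#' Composition of the block: anchor-line features are bilinearly sampled
#' from the map, projected and scattered back as the query map; dense
#' key/value projections feed dual-axis attention; the detail gate is
#' fused as gate * y + y; and the fused map is sampled at the anchor
#' points, yielding one enriched feature per anchor sample position.
#'
#' @param fmap H x W x C feature map.
#' @param anchor_points N x 2 matrix of (x, y) positions in feature px.
#' @param cfg a [dae_config()] (its `mode` selects dae / full / off).
#' @param params weights from [init_dae_params()].
#' @return N x C matrix of enriched features.
#' @export
attention_roi_align <- function(fmap, anchor_points, cfg, params) {
  d <- dim(fmap); H <- d[1]; W <- d[2]; C <- d[3]
  anchor_points <- as.matrix(anchor_points)
  fm <- fm_from_array(fmap)
  bc <- bilinear_coeffs(anchor_points, H, W)
  gather <- function(m) {
    out <- bc$wt[, 1] * m[bc$ix[, 1], , drop = FALSE]
    for (j in 2:4) out <- out + bc$wt[, j] * m[bc$ix[, j], , drop = FALSE]
    out
  }
  line_feats <- gather(fm)                            # N x C
  if (cfg$mode == "off") return(line_feats)
  if (cfg$v_channels != C)
    cr_stop("fused ROI align requires v_channels == in_channels",
            "croprows_contract_violation")
  qmap <- scatter_line_query(line_feats %*% params$Wq_s, anchor_points, H, W)
  kmap <- fm_to_array(fm %*% params$Wk_s, H, W)
  vmap <- fm_to_array(fm %*% params$Wv_s, H, W)
  y <- if (cfg$mode == "full") full_attention_reference(qmap, kmap, vmap)
       else dual_axis_attention(qmap, kmap, vmap)
  gate <- detail_enhancement_gate(line_feats,
                                  fm_to_array(fm %*% params$Wk_e, H, W),
                                  fm_to_array(fm %*% params$Wv_e, H, W),
                                  cfg, params)
  fused <- gate * y + y
  gather(fm_from_array(fused))
}
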
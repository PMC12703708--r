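# Minimal reverse-mode autodiff on a linear tape.
#
# Values are numeric matrices. Feature maps are stored "feature-matrix"
# style: a (B*H*W) x C matrix whose rows run image-major, then scanline
# (y), then column (x); spatial metadata travels separately. Convolutions
# are im2col + GEMM so the heavy lifting stays in BLAS. Nodes are
# environments; backward walks the tape in reverse creation order.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

node_new <- function(tape, val, prev = list(), back = NULL, track = FALSE,
                     param = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$prev <- prev
  nd$back <- back
  nd$track <- track || !is.null(param)
  nd$param <- param
  if (nd$track) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes))
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    tape$nodes[[tape$n]] <- nd
    nd$tid <- tape$n
  }
  nd
}

is_node <- function(x) is.environment(x) && !is.null(x$val)

as_node <- function(tape, x) {
  if (is_node(x)) return(x)
  node_new(tape, as.matrix(x))
}

node_tracked <- function(...) {
  for (x in list(...)) if (is_node(x) && x$track) return(TRUE)
  FALSE
}

#' Trainable parameter store
#'
#' A persistent environment holding a weight matrix, its accumulated
#' gradient and AdamW moment buffers. Wrapped into a tape as a leaf node
#' on every forward pass.
#'
#' @param val initial numeric matrix/array value.
#' @param name optional identifier.
#' @return a parameter environment.
#' @export
param_new <- function(val, name = NULL) {
  p <- new.env(parent = emptyenv())
  p$val <- as.matrix(val)
  p$grad <- NULL
  p$m <- NULL
  p$v <- NULL
  p$name <- name
  class(p) <- "croprows_param"
  p
}

leaf <- function(tape, p) node_new(tape, p$val, param = p)

#' Run backpropagation through a tape
#'
#' Seeds the loss node with gradient 1 and accumulates gradients into
#' every tracked node and into the `grad` slot of parameter stores.
#'
#' @param tape a tape from `tape_new()`.
#' @param loss scalar-valued node.
#' @export
backward <- function(tape, loss) {
  loss$grad <- matrix(1, 1, 1)
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad)) next
    if (!is.null(nd$back)) {
      gs <- nd$back(nd)
      for (j in seq_along(nd$prev)) {
        pj <- nd$prev[[j]]
        if (is_node(pj) && pj$track && !is.null(gs[[j]]))
          pj$grad <- if (is.null(pj$grad)) gs[[j]] else pj$grad + gs[[j]]
      }
    }
    if (!is.null(nd$param)) {
      p <- nd$param
      p$grad <- if (is.null(p$grad)) nd$grad else p$grad + nd$grad
    }
  }
  invisible(NULL)
}

# ---- elementwise / linear ops ------------------------------------------

op_add <- function(tape, a, b) {
  a <- as_node(tape, a); b <- as_node(tape, b)
  node_new(tape, a$val + b$val, list(a, b),
           function(nd) list(nd$grad, nd$grad), node_tracked(a, b))
}

op_sub <- function(tape, a, b) {
  a <- as_node(tape, a); b <- as_node(tape, b)
  node_new(tape, a$val - b$val, list(a, b),
           function(nd) list(nd$grad, -nd$grad), node_tracked(a, b))
}

op_mul <- function(tape, a, b) {
  a <- as_node(tape, a); b <- as_node(tape, b)
  node_new(tape, a$val * b$val, list(a, b),
           function(nd) list(nd$grad * b$val, nd$grad * a$val),
           node_tracked(a, b))
}

op_scale <- function(tape, a, s) {
  a <- as_node(tape, a)
  node_new(tape, a$val * s, list(a), function(nd) list(nd$grad * s), a$track)
}

op_matmul <- function(tape, a, b) {
  a <- as_node(tape, a); b <- as_node(tape, b)
  node_new(tape, a$val %*% b$val, list(a, b),
           function(nd) list(nd$grad %*% t(b$val), crossprod(a$val, nd$grad)),
           node_tracked(a, b))
}

# a %*% t(b)
op_matmul_nt <- function(tape, a, b) {
  a <- as_node(tape, a); b <- as_node(tape, b)
  node_new(tape, tcrossprod(a$val, b$val), list(a, b),
           function(nd) list(nd$grad %*% b$val, crossprod(nd$grad, a$val)),
           node_tracked(a, b))
}

op_bias <- function(tape, a, b) {  # add row vector b to every row of a
  a <- as_node(tape, a); b <- as_node(tape, b)
  node_new(tape, sweep(a$val, 2, as.vector(b$val), "+"), list(a, b),
           function(nd) list(nd$grad, matrix(colSums(nd$grad), 1)),
           node_tracked(a, b))
}

op_relu <- function(tape, a) {
  a <- as_node(tape, a)
  v <- a$val; v[v < 0] <- 0
  node_new(tape, v, list(a),
           function(nd) list(nd$grad * (a$val > 0)), a$track)
}

op_sigmoid <- function(tape, a) {
  a <- as_node(tape, a)
  s <- 1 / (1 + exp(-a$val))
  node_new(tape, s, list(a), function(nd) list(nd$grad * s * (1 - s)), a$track)
}

op_clamp <- function(tape, a, lo, hi) {
  a <- as_node(tape, a)
  node_new(tape, clamp(a$val, lo, hi), list(a),
           function(nd) list(nd$grad * (a$val > lo & a$val < hi)), a$track)
}

op_cot <- function(tape, a) {  # cos/sin with derivative -1/sin^2
  a <- as_node(tape, a)
  node_new(tape, cos(a$val) / sin(a$val), list(a),
           function(nd) list(-nd$grad / sin(a$val)^2), a$track)
}

op_softmax_rows <- function(tape, a) {
  a <- as_node(tape, a)
  z <- a$val - apply(a$val, 1, max)
  e <- exp(z)
  s <- e / rowSums(e)
  node_new(tape, s, list(a),
           function(nd) list(s * (nd$grad - rowSums(nd$grad * s))), a$track)
}

op_mean_all <- function(tape, a) {
  a <- as_node(tape, a)
  n <- length(a$val)
  node_new(tape, matrix(mean(a$val), 1, 1), list(a),
           function(nd) list(array(nd$grad[1] / n, dim(a$val))), a$track)
}

op_sum_all <- function(tape, a) {
  a <- as_node(tape, a)
  node_new(tape, matrix(sum(a$val), 1, 1), list(a),
           function(nd) list(array(nd$grad[1], dim(a$val))), a$track)
}

# broadcast a column (n x 1) across k columns
op_bcast_col <- function(tape, a, k) {
  a <- as_node(tape, a)
  node_new(tape, matrix(a$val, nrow(a$val), k), list(a),
           function(nd) list(matrix(rowSums(nd$grad), ncol = 1)), a$track)
}

op_concat_cols <- function(tape, xs) {
  xs <- lapply(xs, as_node, tape = tape)
  widths <- vapply(xs, function(x) ncol(x$val), 1L)
  node_new(tape, do.call(cbind, lapply(xs, function(x) x$val)), xs,
           function(nd) {
             out <- vector("list", length(xs)); at <- 0L
             for (j in seq_along(xs)) {
               out[[j]] <- nd$grad[, at + seq_len(widths[j]), drop = FALSE]
               at <- at + widths[j]
             }
             out
           }, do.call(node_tracked, xs))
}

op_rbind <- function(tape, xs) {
  xs <- lapply(xs, as_node, tape = tape)
  hs <- vapply(xs, function(x) nrow(x$val), 1L)
  node_new(tape, do.call(rbind, lapply(xs, function(x) x$val)), xs,
           function(nd) {
             out <- vector("list", length(xs)); at <- 0L
             for (j in seq_along(xs)) {
               out[[j]] <- nd$grad[at + seq_len(hs[j]), , drop = FALSE]
               at <- at + hs[j]
             }
             out
           }, do.call(node_tracked, xs))
}

op_cols_select <- function(tape, a, idx) {
  a <- as_node(tape, a)
  node_new(tape, a$val[, idx, drop = FALSE], list(a),
           function(nd) {
             g <- matrix(0, nrow(a$val), ncol(a$val))
             g[, idx] <- nd$grad
             list(g)
           }, a$track)
}

# select rows (idx may repeat); gradient scatter-adds
op_rows_select <- function(tape, a, idx) {
  a <- as_node(tape, a)
  node_new(tape, a$val[idx, , drop = FALSE], list(a),
           function(nd) {
             g <- matrix(0, nrow(a$val), ncol(a$val))
             rs <- rowsum(nd$grad, idx, reorder = TRUE)
             ui <- sort(unique(idx))
             g[ui, ] <- rs
             list(g)
           }, a$track)
}

# ---- spatial ops on feature matrices -----------------------------------

.conv_cache <- new.env(parent = emptyenv())

# im2col source-row indices for shape (B,H,W), kernel k, stride s, pad p.
# Entry [m, j] is the padded-input row feeding output pixel m through
# kernel tap j; B*H*W + 1 addresses the zero (padding) row.
conv_indices <- function(B, H, W, k, stride, pad) {
  key <- paste(B, H, W, k, stride, pad, sep = "_")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  OH <- (H + 2 * pad - k) %/% stride + 1L
  OW <- (W + 2 * pad - k) %/% stride + 1L
  M0 <- OH * OW
  oy <- rep.int(0:(OH - 1L), rep.int(OW, OH))
  ox <- rep.int(0:(OW - 1L), OH)
  G0 <- matrix(0L, M0, k * k)
  pad_mark <- matrix(FALSE, M0, k * k)
  j <- 0L
  for (dy in 0:(k - 1L)) for (dx in 0:(k - 1L)) {
    j <- j + 1L
    iy <- oy * stride + dy - pad
    ix <- ox * stride + dx - pad
    bad <- iy < 0L | iy >= H | ix < 0L | ix >= W
    v <- iy * W + ix + 1L
    v[bad] <- 0L
    G0[, j] <- v
    pad_mark[, j] <- bad
  }
  HW <- as.integer(H * W)
  G <- G0[rep.int(seq_len(M0), B), , drop = FALSE] +
    rep.int((0:(B - 1L)) * HW, rep.int(M0, B))
  G[pad_mark[rep.int(seq_len(M0), B), ]] <- B * HW + 1L
  out <- list(G = G, Gv = as.vector(G), OH = OH, OW = OW)
  .conv_cache[[key]] <- out
  out
}

# 2D convolution. x: (B*H*W) x Cin; Wt: (Cin*k*k) x Cout with row layout
# (cin - 1)*k^2 + tap (channel-major, matching the zero-copy im2col
# reshape); b: 1 x Cout bias or NULL.
op_conv2d <- function(tape, x, Wt, b, B, H, W, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  x <- as_node(tape, x); Wt <- as_node(tape, Wt)
  ci <- conv_indices(B, H, W, k, stride, pad)
  G <- ci$G
  M <- nrow(G); k2 <- k * k
  Cin <- ncol(x$val)
  Xp <- rbind(x$val, 0)
  cols <- Xp[ci$Gv, , drop = FALSE]          # (M*k2) x Cin
  dim(cols) <- c(M, k2 * Cin)                # zero-copy: col q = (cin-1)*k2 + j
  out <- cols %*% Wt$val
  if (!is.null(b)) {
    b <- as_node(tape, b)
    out <- sweep(out, 2, as.vector(b$val), "+")
  }
  prev <- if (is.null(b)) list(x, Wt) else list(x, Wt, b)
  nd <- node_new(tape, out, prev,
    function(nd) {
      g <- nd$grad
      dW <- crossprod(cols, g)
      dcols <- g %*% t(Wt$val)               # M x (k2*Cin)
      dim(dcols) <- c(M * k2, Cin)
      dx <- matrix(0, nrow(x$val), Cin)
      n_real <- nrow(x$val)
      # per kernel tap the output -> input pixel map is injective, so a
      # direct indexed add is safe (no duplicate accumulation)
      for (j in seq_len(k2)) {
        idx <- G[, j]
        ok <- idx <= n_real
        if (!any(ok)) next
        blk <- dcols[(j - 1L) * M + which(ok), , drop = FALSE]
        ii <- idx[ok]
        dx[ii, ] <- dx[ii, ] + blk
      }
      gs <- list(dx, dW)
      if (!is.null(b)) gs <- c(gs, list(matrix(colSums(g), 1)))
      gs
    }, node_tracked(x, Wt, b))
  attr(nd$val, "OH") <- ci$OH; attr(nd$val, "OW") <- ci$OW
  nd
}

# 1D convolution (same padding) along length-N sequences stacked as
# (n_seq*N) x C rows; im2col over the sequence axis only.
op_conv1d <- function(tape, x, Wt, b, n_seq, N, k = 3L) {
  x <- as_node(tape, x); Wt <- as_node(tape, Wt)
  pad <- (k - 1L) %/% 2L
  key <- paste("1d", n_seq, N, k, sep = "_")
  ci <- .conv_cache[[key]]
  if (is.null(ci)) {
    pos <- rep(0:(N - 1L), times = n_seq)
    base <- rep((0:(n_seq - 1L)) * N, each = N)
    G <- matrix(0L, n_seq * N, k)
    for (j in 0:(k - 1L)) {
      ip <- pos + j - pad
      ok <- ip >= 0L & ip < N
      G[, j + 1L] <- ifelse(ok, base + ip + 1L, n_seq * N + 1L)
    }
    ci <- list(G = G, Gv = as.vector(G))
    .conv_cache[[key]] <- ci
  }
  G <- ci$G
  M <- nrow(G)
  Cin <- ncol(x$val)
  Xp <- rbind(x$val, 0)
  cols <- Xp[ci$Gv, , drop = FALSE]
  dim(cols) <- c(M, k * Cin)                 # col q = (cin-1)*k + j
  out <- cols %*% Wt$val
  if (!is.null(b)) { b <- as_node(tape, b); out <- sweep(out, 2, as.vector(b$val), "+") }
  prev <- if (is.null(b)) list(x, Wt) else list(x, Wt, b)
  node_new(tape, out, prev,
    function(nd) {
      g <- nd$grad
      dW <- crossprod(cols, g)
      dcols <- g %*% t(Wt$val)
      dim(dcols) <- c(M * k, Cin)
      dx <- matrix(0, nrow(x$val), Cin)
      n_real <- nrow(x$val)
      for (j in seq_len(k)) {       # injective per tap: direct add
        idx <- G[, j]; ok <- idx <= n_real
        if (!any(ok)) next
        blk <- dcols[(j - 1L) * M + which(ok), , drop = FALSE]
        ii <- idx[ok]
        dx[ii, ] <- dx[ii, ] + blk
      }
      gs <- list(dx, dW)
      if (!is.null(b)) gs <- c(gs, list(matrix(colSums(g), 1)))
      gs
    }, node_tracked(x, Wt, b))
}

op_maxpool2 <- function(tape, x, B, H, W) {
  x <- as_node(tape, x)
  ci <- conv_indices(B, H, W, 2L, 2L, 0L)
  G <- ci$G
  M <- nrow(G); C <- ncol(x$val)
  Xp <- rbind(x$val, -Inf)
  best <- Xp[G[, 1], , drop = FALSE]
  arg <- matrix(1L, M, C)
  for (j in 2:4) {
    cand <- Xp[G[, j], , drop = FALSE]
    sel <- cand > best
    best[sel] <- cand[sel]
    arg[sel] <- j
  }
  node_new(tape, best, list(x),
    function(nd) {
      dx <- matrix(0, nrow(x$val), C)
      n_real <- nrow(x$val)
      for (j in 1:4) {              # injective per tap: direct add
        idx <- G[, j]; ok <- idx <= n_real
        mj <- (nd$grad * (arg == j))[ok, , drop = FALSE]
        ii <- idx[ok]
        dx[ii, ] <- dx[ii, ] + mj
      }
      list(dx)
    }, x$track)
}

# nearest-neighbour upsample from (H,W) to (H2,W2), per image
op_upsample_nn <- function(tape, x, B, H, W, H2, W2) {
  x <- as_node(tape, x)
  key <- paste("up", B, H, W, H2, W2, sep = "_")
  idx <- .conv_cache[[key]]
  if (is.null(idx)) {
    sy <- as.integer(pmin(floor((0:(H2 - 1L)) * H / H2), H - 1L))
    sx <- as.integer(pmin(floor((0:(W2 - 1L)) * W / W2), W - 1L))
    id0 <- as.integer(as.vector(t(outer(sy * W, sx, "+"))) + 1L)  # y-major, x fastest
    idx <- as.vector(vapply(seq_len(B), function(b) id0 + (b - 1L) * as.integer(H * W),
                            integer(H2 * W2)))
    .conv_cache[[key]] <- idx
  }
  op_rows_select(tape, x, idx)
}

# bilinear gather of rows at fractional positions; ix: n x 4 integer row
# indices, wt: n x 4 weights (positions are treated as constants)
op_gather_bilinear <- function(tape, x, ix, wt) {
  x <- as_node(tape, x)
  out <- wt[, 1] * x$val[ix[, 1], , drop = FALSE]
  for (j in 2:4) out <- out + wt[, j] * x$val[ix[, j], , drop = FALSE]
  node_new(tape, out, list(x),
    function(nd) {
      dx <- matrix(0, nrow(x$val), ncol(x$val))
      for (j in 1:4) {
        rs <- rowsum(nd$grad * wt[, j], ix[, j], reorder = TRUE)
        ui <- sort(unique(ix[, j]))
        dx[ui, ] <- dx[ui, ] + rs
      }
      list(dx)
    }, x$track)
}

# bilinear scatter (transpose of gather) of n features onto n_out rows
op_scatter_bilinear <- function(tape, feats, ix, wt, n_out) {
  feats <- as_node(tape, feats)
  C <- ncol(feats$val)
  out <- matrix(0, n_out, C)
  for (j in 1:4) {
    rs <- rowsum(feats$val * wt[, j], ix[, j], reorder = TRUE)
    ui <- sort(unique(ix[, j]))
    out[ui, ] <- out[ui, ] + rs
  }
  node_new(tape, out, list(feats),
    function(nd) {
      g <- wt[, 1] * nd$grad[ix[, 1], , drop = FALSE]
      for (j in 2:4) g <- g + wt[, j] * nd$grad[ix[, j], , drop = FALSE]
      list(g)
    }, feats$track)
}

# group-mean over rows (e.g. axis squeeze): group is an integer vector,
# values 1..ngroup, each appearing cnt[g] times
op_groupmean <- function(tape, x, group, ngroup) {
  x <- as_node(tape, x)
  cnt <- tabulate(group, ngroup)
  out <- rowsum(x$val, group) / cnt
  node_new(tape, out, list(x),
    function(nd) list(nd$grad[group, , drop = FALSE] / cnt[group]),
    x$track)
}

# per-(image, channel) spatial standardization with shared per-channel
# affine: the package's normalization layer
op_instnorm <- function(tape, x, gamma, beta, group, eps = 1e-5) {
  x <- as_node(tape, x); gamma <- as_node(tape, gamma); beta <- as_node(tape, beta)
  ngroup <- max(group)
  cnt <- tabulate(group, ngroup)
  mu <- rowsum(x$val, group) / cnt
  xc <- x$val - mu[group, , drop = FALSE]
  va <- rowsum(xc * xc, group) / cnt
  istd <- 1 / sqrt(va + eps)
  y <- xc * istd[group, , drop = FALSE]
  gv <- as.vector(gamma$val); bv <- as.vector(beta$val)
  out <- sweep(sweep(y, 2, gv, "*"), 2, bv, "+")
  node_new(tape, out, list(x, gamma, beta),
    function(nd) {
      g <- nd$grad
      ghat <- sweep(g, 2, gv, "*")
      mg <- rowsum(ghat, group) / cnt
      mgy <- rowsum(ghat * y, group) / cnt
      dx <- istd[group, , drop = FALSE] *
        (ghat - mg[group, , drop = FALSE] - y * mgy[group, , drop = FALSE])
      list(dx, matrix(colSums(g * y), 1), matrix(colSums(g), 1))
    }, node_tracked(x, gamma, beta))
}

# ---- loss ops -----------------------------------------------------------

# focal classification loss from logits; pos is a logical matrix of the
# same shape; returns elementwise losses
op_focal_logits <- function(tape, z, pos, alpha = 0.25, gamma = 2) {
  z <- as_node(tape, z)
  p <- clamp(1 / (1 + exp(-z$val)), 1e-7, 1 - 1e-7)
  val <- ifelse(pos, -alpha * (1 - p)^gamma * log(p),
                -(1 - alpha) * p^gamma * log(1 - p))
  node_new(tape, val, list(z),
    function(nd) {
      dLdp <- ifelse(pos,
                     -alpha * (-gamma * (1 - p)^(gamma - 1) * log(p) + (1 - p)^gamma / p),
                     -(1 - alpha) * (gamma * p^(gamma - 1) * log(1 - p) - p^gamma / (1 - p)))
      list(nd$grad * dLdp * p * (1 - p))
    }, z$track)
}

# elementwise smooth-l1 of a difference node
op_smooth_l1 <- function(tape, d, beta = 1) {
  d <- as_node(tape, d)
  a <- abs(d$val)
  val <- ifelse(a < beta, 0.5 * d$val^2 / beta, a - 0.5 * beta)
  node_new(tape, val, list(d),
    function(nd) list(nd$grad * ifelse(a < beta, d$val / beta, sign(d$val))),
    d$track)
}

# mean Row-IoU loss over P rows; xs: P x N node of predicted abscissae,
# gt_xs / gt_valid: constant P x N matrices, e: extension half-length
op_riou_rows <- function(tape, xs, gt_xs, gt_valid, e, eps = 1e-9) {
  xs <- as_node(tape, xs)
  P <- nrow(gt_xs)
  d <- abs(xs$val - gt_xs) * gt_valid
  nv <- rowSums(gt_valid)
  O <- rowSums((2 * e) * gt_valid - d)
  U <- rowSums((2 * e) * gt_valid + d) + eps
  val <- matrix(1 - O / U, ncol = 1)
  node_new(tape, val, list(xs),
    function(nd) {
      s <- sign(xs$val - gt_xs) * gt_valid
      gper <- as.vector(nd$grad) * (U + O) / U^2
      list(s * gper)
    }, xs$track)
}

# ---- optimizer ----------------------------------------------------------

#' One AdamW update over a list of parameter stores
#'
#' @param params list of [param_new()] environments.
#' @param lr learning rate.
#' @param beta1,beta2,eps Adam moment parameters.
#' @param weight_decay decoupled weight decay.
#' @param t step counter (1-based) for bias correction.
#' @export
adamw_step <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_decay = 0.01, t = 1) {
  for (p in params) {
    if (is.null(p$grad)) next
    if (is.null(p$m)) { p$m <- p$grad * 0; p$v <- p$grad * 0 }
    p$m <- beta1 * p$m + (1 - beta1) * p$grad
    p$v <- beta2 * p$v + (1 - beta2) * p$grad^2
    mh <- p$m / (1 - beta1^t)
    vh <- p$v / (1 - beta2^t)
    p$val <- p$val - lr * (mh / (sqrt(vh) + eps) + weight_decay * p$val)
    p$grad <- NULL
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
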
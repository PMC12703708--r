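# Internal helpers shared across modules.

cr_stop <- function(msg, class) {
  stop(structure(class = c(class, "croprows_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a per-item seed from a master seed
#'
#' Splitmix-style integer hash so that items (images, epochs, seeds of
#' sub-runs) get reproducible, well-separated RNG streams while staying
#' below 2^31.
#'
#' @param master integer master seed.
#' @param index nonnegative integer item index.
#' @return an integer seed in [0, 2^31).
#' @export
derive_seed <- function(master, index) {
  x <- (as.double(master) * 48271 + as.double(index) * 16807 + 12345) %% 2147483647
  x <- (x * 69621) %% 2147483647
  as.integer(x)
}

# Bilinear resize of an H x W (x C) numeric array to to_h x to_w.
bilinear_resize <- function(img, to_w, to_h) {
  d <- dim(img)
  h <- d[1]; w <- d[2]
  nc <- if (length(d) == 3) d[3] else 1L
  if (h == to_h && w == to_w) return(img)
  # map output pixel centers to input pixel centers
  sy <- h / to_h; sx <- w / to_w
  ys <- clamp((seq_len(to_h) - 0.5) * sy - 0.5, 0, h - 1)
  xs <- clamp((seq_len(to_w) - 0.5) * sx - 0.5, 0, w - 1)
  y0 <- floor(ys); x0 <- floor(xs)
  y1 <- pmin(y0 + 1, h - 1); x1 <- pmin(x0 + 1, w - 1)
  wy <- ys - y0; wx <- xs - x0
  i0 <- y0 + 1L; i1 <- y1 + 1L; j0 <- x0 + 1L; j1 <- x1 + 1L
  out <- array(0, c(to_h, to_w, nc))
  im <- if (length(d) == 3) img else array(img, c(h, w, 1L))
  for (c in seq_len(nc)) {
    p <- im[, , c]
    a <- p[i0, j0, drop = FALSE] * outer(1 - wy, 1 - wx)
    b <- p[i0, j1, drop = FALSE] * outer(1 - wy, wx)
    cc <- p[i1, j0, drop = FALSE] * outer(wy, 1 - wx)
    dd <- p[i1, j1, drop = FALSE] * outer(wy, wx)
    out[, , c] <- a + b + cc + dd
  }
  if (length(d) == 3) out else out[, , 1]
}

# Separable Gaussian blur on an H x W (x C) array; sigma in px.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(2.5 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(img)
  nc <- if (length(d) == 3) d[3] else 1L
  im <- if (length(d) == 3) img else array(img, c(d[1], d[2], 1L))
  blur1 <- function(m, along) {
    # shift-and-add with edge replication
    n <- if (along == 1) nrow(m) else ncol(m)
    acc <- m * 0
    for (s in seq(-r, r)) {
      idx <- clamp(seq_len(n) + s, 1, n)
      acc <- acc + k[s + r + 1] * (if (along == 1) m[idx, , drop = FALSE] else m[, idx, drop = FALSE])
    }
    acc
  }
  out <- im
  for (c in seq_len(nc)) out[, , c] <- blur1(blur1(im[, , c], 1), 2)
  if (length(d) == 3) out else out[, , 1]
}

# Run expr with a local RNG state seeded by `seed`; restores global state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) base::assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
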
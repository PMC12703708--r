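# Row geometry: polylines, uniformly sampled rows, anchor-line priors, and the
# conversions among them. Coordinates use the raster convention: origin at the
# top-left corner, x rightward, y downward, continuous (sub-pixel) pixel units.

#' Annotated crop-row centerline
#'
#' An ordered polyline tracing one crop row, as produced by polyline
#' annotation of a field image. Points must run top to bottom (strictly
#' increasing y) and lie inside the image frame.
#'
#' @param points numeric matrix with two columns (x, y), at least two rows.
#' @param image_width,image_height image dimensions in pixels.
#' @param label character label for the row instance.
#' @return an object of class `row_polyline`.
#' @export
row_polyline <- function(points, image_width, image_height, label = "row") {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2 || nrow(points) < 2)
    cr_stop("polyline needs a numeric n x 2 matrix with n >= 2", "croprows_invalid_input")
  if (any(!is.finite(points)))
    cr_stop("polyline points must be finite", "croprows_invalid_input")
  if (any(diff(points[, 2]) <= 0))
    cr_stop("polyline y-coordinates must be strictly increasing", "croprows_invalid_input")
  if (any(points[, 1] < 0 | points[, 1] > image_width) ||
      any(points[, 2] < 0 | points[, 2] > image_height))
    cr_stop("polyline points must lie within the image frame", "croprows_invalid_input")
  structure(list(points = unname(points), image_width = image_width,
                 image_height = image_height, label = label),
            class = "row_polyline")
}

#' Row discretized at uniform vertical positions
#'
#' A crop row represented by its horizontal position at N equally spaced
#' scanlines y_i = H/(N-1) * i, i = 0..N-1. Positions where the row is not
#' defined carry `valid = FALSE`.
#'
#' @param xs numeric vector of horizontal positions (px), length N.
#' @param valid logical vector, length N.
#' @param height image height H in px (defines the sampling scanlines).
#' @return an object of class `sampled_row`.
#' @export
sampled_row <- function(xs, valid, height) {
  if (length(xs) != length(valid))
    cr_stop("xs and valid must have equal length", "croprows_invalid_input")
  if (any(valid & !is.finite(xs)))
    cr_stop("xs must be finite wherever valid", "croprows_invalid_input")
  structure(list(xs = as.numeric(xs), valid = as.logical(valid),
                 n_points = length(xs), height = height),
            class = "sampled_row")
}

#' Sampling scanline positions of a sampled row
#'
#' @param n_points number of scanlines N.
#' @param height image height H in px.
#' @return numeric vector y_i = H/(N-1) * i for i = 0..N-1.
#' @export
sample_ys <- function(n_points, height) height / (n_points - 1) * (seq_len(n_points) - 1)

#' Learnable straight-line prior for one crop row
#'
#' Parameterized by its bottom end (largest y), its direction angle theta
#' measured from the positive x-axis (radians, strictly inside (0, pi), so
#' the line is never parallel to a scanline), and a real-valued length
#' counted in valid sample rows.
#'
#' @param start_x,start_y bottom-end coordinates in px.
#' @param theta direction angle in radians, in (0, pi).
#' @param length number of valid sample rows covered (real-valued; rounded
#'   up only when gating validity).
#' @return an object of class `anchor_line`.
#' @export
anchor_line <- function(start_x, start_y, theta, length) {
  if (!is.finite(theta) || theta <= 0 || theta >= pi)
    cr_stop("anchor theta must lie strictly inside (0, pi)", "croprows_invalid_anchor")
  if (!is.finite(length) || length < 0)
    cr_stop("anchor length must be nonnegative", "croprows_invalid_anchor")
  structure(list(start_x = start_x, start_y = start_y,
                 theta = theta, length = length),
            class = "anchor_line")
}

#' Scored row prediction
#'
#' @param score detection probability in [0, 1].
#' @param anchor an [anchor_line()].
#' @param offsets numeric length-N vector of horizontal displacements (px)
#'   from the anchor's straight reference line at each scanline.
#' @return an object of class `row_prediction`.
#' @export
row_prediction <- function(score, anchor, offsets) {
  if (!is.finite(score) || score < 0 || score > 1)
    cr_stop("score must lie in [0, 1]", "croprows_invalid_input")
  if (any(!is.finite(offsets)))
    cr_stop("offsets must be finite", "croprows_invalid_input")
  structure(list(score = score, anchor = anchor, offsets = as.numeric(offsets)),
            class = "row_prediction")
}

#' Discretize a row polyline at uniform scanlines
#'
#' Linearly interpolates the polyline at the N scanlines y_i = H/(N-1) * i.
#' Scanlines outside the polyline's vertical span are marked invalid. The
#' bottom scanline y = H is nudged down by a tiny epsilon for raster safety.
#'
#' @param polyline a [row_polyline()].
#' @param n_points number of scanlines N (>= 2).
#' @param height image height H in px.
#' @return a [sampled_row()].
#' @export
sample_row <- function(polyline, n_points, height) {
  stopifnot(inherits(polyline, "row_polyline"), n_points >= 2, height > 0)
  p <- polyline$points
  if (diff(range(p[, 2])) <= 0)
    cr_stop("degenerate polyline: zero vertical extent", "croprows_invalid_input")
  ys <- sample_ys(n_points, height)
  ys <- pmin(ys, height - 1e-9)   # raster safety at the bottom scanline
  valid <- ys >= p[1, 2] & ys <= p[nrow(p), 2]
  xs <- rep(NA_real_, n_points)
  if (any(valid))
    xs[valid] <- stats::approx(p[, 2], p[, 1], xout = ys[valid], ties = "ordered")$y
  xs[!valid] <- 0
  sampled_row(xs, valid, height)
}

#' Realize a sampled row from an anchor line plus per-scanline offsets
#'
#' The anchor's straight reference line gives x_ref(i) = start_x +
#' (start_y - y_i) / tan(theta); the realized row is x_ref + offsets.
#' Validity covers the ceiling(length) scanlines at or above start_y,
#' counted upward from the scanline nearest start_y.
#'
#' @param anchor an [anchor_line()].
#' @param offsets numeric length-N vector (px).
#' @param n_points number of scanlines N.
#' @param height image height H in px.
#' @return a [sampled_row()].
#' @export
anchor_to_points <- function(anchor, offsets, n_points, height) {
  if (!inherits(anchor, "anchor_line"))
    cr_stop("anchor must be an anchor_line", "croprows_invalid_anchor")
  if (length(offsets) != n_points)
    cr_stop("offsets must have length n_points", "croprows_invalid_input")
  ys <- sample_ys(n_points, height)
  xs <- anchor$start_x + (anchor$start_y - ys) / tan(anchor$theta) + offsets
  below <- which(ys <= anchor$start_y)       # candidate scanlines, top..bottom order
  k <- min(ceiling(anchor$length), length(below))
  valid <- rep(FALSE, n_points)
  if (k > 0) valid[below[(length(below) - k + 1):length(below)]] <- TRUE
  xs[!valid & !is.finite(xs)] <- 0
  sampled_row(xs, valid, height)
}

#' Rescale a sampled row between resolutions
#'
#' @param row a [sampled_row()].
#' @param from_w,from_h source resolution (px).
#' @param to_w,to_h target resolution (px).
#' @return a [sampled_row()] at the target resolution.
#' @export
rescale_row <- function(row, from_w, from_h, to_w, to_h) {
  stopifnot(inherits(row, "sampled_row"),
            from_w > 0, from_h > 0, to_w > 0, to_h > 0)
  sampled_row(row$xs * (to_w / from_w), row$valid, to_h)
}
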
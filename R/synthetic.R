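# Synthetic maize-field scene generator. World-parallel row centerlines on a
# flat ground plane are projected through a pinhole camera pitched toward the
# ground, giving converging image-space rows with exact polyline ground truth.
# Plants are green blob clusters along the centerlines; weeds are isotropic
# clutter; photometric perturbations (illumination gain, blur) never touch
# the ground-truth polylines.

#' Synthetic scene configuration
#'
#' Defaults emulate handheld-gimbal capture over mechanically sown maize at
#' the 3-5 leaf stage: 1280x720 frames, camera pitched 45 degrees below the
#' horizon (30/45/60 are the emulated choices), parallel rows 0.6 world
#' units apart, plants every 0.25 units with occasional seedling gaps, weed
#' clutter, variable illumination, optional motion blur, and wind-lodging
#' jitter of plant positions about the row centerline.
#'
#' @param image_width,image_height frame size in px.
#' @param n_rows number of world rows.
#' @param row_spacing_world lateral row spacing (world units; metres).
#' @param camera_pitch_deg camera pitch below the horizon, degrees.
#' @param plant_spacing along-row plant spacing (world units).
#' @param plant_radius length-2 px range of plant blob radii (far, near).
#' @param weed_density weed blobs per kilopixel.
#' @param gap_probability probability a plant is missing (seedling gap).
#' @param illumination_gain length-2 multiplicative gain range.
#' @param blur_sigma Gaussian blur sigma in px (0 disables).
#' @param lodging_shear lateral px jitter of plant blobs (wind lodging).
#' @param camera_height camera height above ground (world units).
#' @param focal_px pinhole focal length in px (defaults to 0.9 * width).
#' @param seed integer RNG seed; output is deterministic given the config.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(image_width = 1280, image_height = 720,
                         n_rows = 5, row_spacing_world = 0.6,
                         camera_pitch_deg = 45, plant_spacing = 0.25,
                         plant_radius = c(4, 16), weed_density = 0.08,
                         gap_probability = 0.1,
                         illumination_gain = c(0.7, 1.3),
                         blur_sigma = 0.6, lodging_shear = 2,
                         camera_height = 1.5, focal_px = NULL,
                         seed = 1L) {
  stopifnot(n_rows >= 1, gap_probability >= 0, gap_probability <= 1,
            image_width > 0, image_height > 0, camera_pitch_deg > 0,
            camera_pitch_deg < 90)
  if (is.null(focal_px)) focal_px <- 0.9 * image_width
  structure(list(image_width = image_width, image_height = image_height,
                 n_rows = n_rows, row_spacing_world = row_spacing_world,
                 camera_pitch_deg = camera_pitch_deg,
                 plant_spacing = plant_spacing, plant_radius = plant_radius,
                 weed_density = weed_density, gap_probability = gap_probability,
                 illumination_gain = illumination_gain, blur_sigma = blur_sigma,
                 lodging_shear = lodging_shear, camera_height = camera_height,
                 focal_px = focal_px, seed = as.integer(seed)),
            class = "scene_config")
}

# Project world ground-plane points (X, Y, 0) through the pinhole camera.
# Camera at (0, 0, hc) looking along +Y, pitched `phi` below the horizon.
# Returns cbind(u, v, z) with z the camera-frame depth.
project_ground <- function(X, Y, cfg) {
  phi <- cfg$camera_pitch_deg * pi / 180
  hc <- cfg$camera_height
  z <- Y * cos(phi) + hc * sin(phi)
  u <- cfg$focal_px * X / z + cfg$image_width / 2
  v <- cfg$focal_px * (hc * cos(phi) - Y * sin(phi)) / z + cfg$image_height / 2
  cbind(u, v, z)
}

# Clip the image-space segment (p0, p1) to the frame rectangle
# [0, W] x [0, H] (Liang-Barsky). Returns NULL or a 2 x 2 matrix.
clip_segment <- function(p0, p1, W, H) {
  d <- p1 - p0
  t0 <- 0; t1 <- 1
  for (k in 1:4) {
    p <- c(-d[1], d[1], -d[2], d[2])[k]
    q <- c(p0[1], W - p0[1], p0[2], H - p0[2])[k]
    if (p == 0) { if (q < 0) return(NULL) } else {
      t <- q / p
      if (p < 0) { if (t > t1) return(NULL); if (t > t0) t0 <- t }
      else { if (t < t0) return(NULL); if (t < t1) t1 <- t }
    }
  }
  rbind(p0 + t0 * d, p0 + t1 * d)
}

# Paint a filled rotated ellipse onto img (H x W x 3), in place via return.
paint_ellipse <- function(img, cx, cy, a, b, angle, col) {
  H <- dim(img)[1]; W <- dim(img)[2]
  r <- max(a, b)
  x0 <- max(1L, floor(cx - r)); x1 <- min(W, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(H, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- (x0:x1) - 0.5 - cx
  ys <- (y0:y1) - 0.5 - cy
  ca <- cos(angle); sa <- sin(angle)
  u <- outer(ys * sa, xs * ca, "+")         # rotated coords
  w <- outer(ys * ca, xs * -sa, "+")
  inside <- (u / a)^2 + (w / b)^2 <= 1
  if (!any(inside)) return(img)
  for (c in 1:3) {
    patch <- img[y0:y1, x0:x1, c]
    patch[inside] <- col[c]
    img[y0:y1, x0:x1, c] <- patch
  }
  img
}

#' Generate one synthetic field scene
#'
#' @param cfg a [scene_config()].
#' @return list with `image` (H x W x 3 array in [0, 1]) and `rows`
#'   (list of [row_polyline()] ground-truth centerlines, exact to the
#'   projection and unaffected by photometric perturbations).
#' @export
generate_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  with_seed(cfg$seed, generate_scene_impl(cfg))
}

generate_scene_impl <- function(cfg) {
  W <- cfg$image_width; H <- cfg$image_height
  offsets <- (seq_len(cfg$n_rows) - (cfg$n_rows + 1) / 2) * cfg$row_spacing_world
  offsets <- offsets + stats::runif(1, -0.5, 0.5) * cfg$row_spacing_world

  # ground-truth centerlines: straight world lines project to straight
  # image lines; clip the projected segment to the frame
  y_near <- 0.05; y_far <- 60
  rows <- list(); row_x <- list()
  for (k in seq_len(cfg$n_rows)) {
    pr <- project_ground(c(offsets[k], offsets[k]), c(y_near, y_far), cfg)
    seg <- clip_segment(pr[1, 1:2], pr[2, 1:2], W, H)
    if (is.null(seg)) next
    seg[, 1] <- clamp(seg[, 1], 0, W)   # guard float round-off at the border
    seg[, 2] <- clamp(seg[, 2], 0, H)
    seg <- seg[order(seg[, 2]), , drop = FALSE]
    if (seg[2, 2] - seg[1, 2] < 2) next      # nearly horizontal sliver
    rows[[length(rows) + 1]] <-
      row_polyline(seg, W, H, label = sprintf("row_%d", length(rows) + 1))
    row_x[[length(rows)]] <- offsets[k]
  }
  if (length(rows) == 0)
    cr_stop("configuration yields zero visible rows", "croprows_invalid_config")

  # soil background with mild texture
  base <- c(0.45, 0.34, 0.23)
  tex <- matrix(stats::runif(H * W, -0.05, 0.05), H, W)
  tex <- tex + gaussian_blur(matrix(stats::runif(H * W, -0.12, 0.12), H, W), 6)
  img <- array(0, c(H, W, 3))
  for (c in 1:3) img[, , c] <- clamp(base[c] + tex, 0, 1)

  # depth range visible in frame, for radius attenuation
  phi <- cfg$camera_pitch_deg * pi / 180
  z_near_frame <- cfg$camera_height * sin(phi)   # depth lower bound
  r0 <- cfg$plant_radius[1]; r1 <- cfg$plant_radius[2]

  # weeds first (plants overdraw them), isotropic single blobs
  n_weeds <- stats::rpois(1, cfg$weed_density * W * H / 1000)
  if (n_weeds > 0) {
    wx <- stats::runif(n_weeds, 0, W); wy <- stats::runif(n_weeds, 0, H)
    wr <- stats::runif(n_weeds, 1.5, 0.45 * r1)
    for (i in seq_len(n_weeds)) {
      col <- c(0.20, 0.45, 0.16) + stats::runif(3, -0.06, 0.06)
      img <- paint_ellipse(img, wx[i], wy[i], wr[i],
                           wr[i] * stats::runif(1, 0.7, 1), stats::runif(1, 0, pi),
                           clamp(col, 0, 1))
    }
  }

  # plants clustered along each centerline (leaf-like elongated lobes)
  for (k in seq_along(rows)) {
    Xw <- row_x[[k]]
    Yj <- seq(0.1, 40, by = cfg$plant_spacing)
    Yj <- Yj + stats::runif(length(Yj), -0.2, 0.2) * cfg$plant_spacing
    keep <- stats::runif(length(Yj)) >= cfg$gap_probability
    pr <- project_ground(rep(Xw, length(Yj)), Yj, cfg)
    vis <- keep & pr[, 3] > 0 & pr[, 1] > -r1 & pr[, 1] < W + r1 &
      pr[, 2] > -r1 & pr[, 2] < H + r1
    shear <- stats::rnorm(length(Yj), 0, cfg$lodging_shear)
    for (i in which(vis)) {
      r <- clamp(r1 * z_near_frame * 3 / pr[i, 3], r0, r1)
      cx <- pr[i, 1] + shear[i]; cy <- pr[i, 2]
      green <- clamp(c(0.16, 0.52, 0.14) + stats::runif(3, -0.05, 0.05), 0, 1)
      n_leaves <- sample(3:5, 1)
      for (l in seq_len(n_leaves)) {
        ang <- stats::runif(1, 0, pi)
        img <- paint_ellipse(img, cx + stats::rnorm(1, 0, 0.25 * r),
                             cy + stats::rnorm(1, 0, 0.25 * r),
                             r * stats::runif(1, 0.8, 1.4), r * stats::runif(1, 0.25, 0.45),
                             ang, clamp(green + stats::runif(3, -0.04, 0.04), 0, 1))
      }
      img <- paint_ellipse(img, cx, cy, 0.45 * r, 0.45 * r, 0,
                           clamp(green * 1.12, 0, 1))
    }
  }

  # photometric perturbations: polylines are never touched
  gain <- stats::runif(1, cfg$illumination_gain[1], cfg$illumination_gain[2])
  img <- clamp(img * gain, 0, 1)
  if (cfg$blur_sigma > 0) img <- clamp(gaussian_blur(img, cfg$blur_sigma), 0, 1)

  list(image = img, rows = rows)
}

#' Generate a dataset of synthetic scenes on disk
#'
#' Writes PNG images and LabelMe JSON annotations plus a JSON-lines
#' manifest. Per-image seeds are derived reproducibly from the config's
#' master seed, so regeneration is byte-identical.
#'
#' @param cfg a [scene_config()]; its `seed` acts as the master seed.
#' @param n_images number of scenes.
#' @param split character tag ("train", "val" or "test") used in filenames.
#' @param out_dir output directory (created if missing).
#' @return data.frame manifest (image, annotation, seed), invisibly also
#'   written to `<split>_manifest.jsonl`.
#' @export
generate_dataset <- function(cfg, n_images, split = "train", out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    cr_stop(paste0("cannot create output directory ", out_dir), "croprows_io_error")
  manifest <- data.frame(image = character(n_images),
                         annotation = character(n_images),
                         seed = integer(n_images))
  for (i in seq_len(n_images)) {
    si <- derive_seed(cfg$seed, i)
    ci <- cfg; ci$seed <- si
    scene <- generate_scene(ci)
    stem <- sprintf("%s_%04d", split, i)
    img_path <- file.path(out_dir, paste0(stem, ".png"))
    ann_path <- file.path(out_dir, paste0(stem, ".json"))
    png::writePNG(scene$image, img_path)
    write_labelme(scene$rows,
                  list(imagePath = basename(img_path),
                       imageWidth = cfg$image_width,
                       imageHeight = cfg$image_height),
                  ann_path)
    manifest$image[i] <- img_path
    manifest$annotation[i] <- ann_path
    manifest$seed[i] <- si
  }
  man_path <- file.path(out_dir, paste0(split, "_manifest.jsonl"))
  con <- file(man_path, "w")
  for (i in seq_len(n_images))
    writeLines(jsonlite::toJSON(as.list(manifest[i, ]), auto_unbox = TRUE), con)
  close(con)
  attr(manifest, "path") <- man_path
  invisible(manifest)
}

#' Read a dataset manifest written by [generate_dataset()]
#'
#' @param path path to a `*_manifest.jsonl` file.
#' @return data.frame with columns image, annotation, seed.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  do.call(rbind, lapply(lines, function(l) {
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
  }))
}
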
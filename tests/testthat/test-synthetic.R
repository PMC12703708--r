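test_that("scene generation is deterministic and respects invariants", {
  cfg <- test_scene_config(seed = 42)
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$rows, s2$rows)

  expect_equal(length(s1$rows), cfg$n_rows)
  for (r in s1$rows) {
    expect_s3_class(r, "row_polyline")
    expect_true(all(diff(r$points[, 2]) > 0))
    expect_true(all(r$points[, 1] >= 0 & r$points[, 1] <= cfg$image_width))
    expect_true(all(r$points[, 2] >= 0 & r$points[, 2] <= cfg$image_height))
  }
  expect_equal(dim(s1$image), c(360, 640, 3))
  expect_true(all(s1$image >= 0 & s1$image <= 1))
})

test_that("photometric perturbations never move the ground truth", {
  base <- test_scene_config(seed = 7, blur_sigma = 0, illumination_gain = c(1, 1))
  pert <- test_scene_config(seed = 7, blur_sigma = 2, illumination_gain = c(0.5, 0.5))
  s_base <- generate_scene(base)
  s_pert <- generate_scene(pert)
  expect_false(identical(s_base$image, s_pert$image))
  # same seed, same geometry stream: identical polylines
  for (k in seq_along(s_base$rows))
    expect_equal(s_base$rows[[k]]$points, s_pert$rows[[k]]$points,
                 tolerance = 1e-12)
})

test_that("lower camera pitch tightens top-of-frame row spacing", {
  top_spacing <- function(pitch) {
    cfg <- test_scene_config(seed = 3, camera_pitch_deg = pitch,
                             n_rows = 3, weed_density = 0, blur_sigma = 0)
    s <- generate_scene(cfg)
    xs_top <- sort(vapply(s$rows, function(r) {
      sr <- sample_row(r, 36, cfg$image_height)
      v <- which(sr$valid)
      sr$xs[v[1]]
    }, 0))
    mean(diff(xs_top))
  }
  sp <- vapply(c(30, 45, 60), top_spacing, 0)
  expect_true(all(diff(sp) > 0))   # steeper pitch -> wider spacing at top
})

test_that("generated ground truth evaluates to a perfect score", {
  cfg <- test_scene_config(seed = 12, n_rows = 4)
  s <- generate_scene(cfg)
  rows <- lapply(s$rows, sample_row, n_points = 36,
                 height = cfg$image_height)
  ec <- eval_config(eval_width = cfg$image_width,
                    eval_height = cfg$image_height)
  ev <- evaluate_dataset(list(rows), list(rows), ec)
  expect_equal(ev$mf1, 100)
})

test_that("datasets regenerate byte-identically and splits differ", {
  d1 <- file.path(tempdir(), "cr_ds_a"); d2 <- file.path(tempdir(), "cr_ds_b")
  cfg <- test_scene_config(seed = 5)
  m1 <- generate_dataset(cfg, 3, "train", d1)
  m2 <- generate_dataset(cfg, 3, "train", d2)
  expect_equal(nrow(m1), 3)
  expect_true(all(file.exists(m1$image)) && all(file.exists(m1$annotation)))
  for (i in 1:3) {
    expect_identical(readBin(m1$image[i], "raw", 1e7),
                     readBin(m2$image[i], "raw", 1e7))
    expect_identical(readLines(m1$annotation[i]), readLines(m2$annotation[i]))
  }
  # a different master seed shares no identical image
  cfg2 <- test_scene_config(seed = 6)
  m3 <- generate_dataset(cfg2, 3, "val", d2)
  h <- function(f) digest_file(f)
  digest_file <- function(f) sum(as.integer(readBin(f, "raw", 1e7)))
  for (i in 1:3)
    expect_false(identical(readBin(m1$image[i], "raw", 1e7),
                           readBin(m3$image[i], "raw", 1e7)))
  # manifest round trip
  mm <- read_manifest(attr(m1, "path"))
  expect_equal(mm$seed, m1$seed)
})

test_that("LabelMe round trip preserves polylines and skips foreign shapes", {
  cfg <- test_scene_config(seed = 9)
  s <- generate_scene(cfg)
  path <- tempfile(fileext = ".json")
  write_labelme(s$rows, list(imagePath = "x.png",
                             imageWidth = cfg$image_width,
                             imageHeight = cfg$image_height), path)
  back <- read_labelme(path)
  expect_equal(length(back), length(s$rows))
  for (k in seq_along(back)) {
    expect_equal(back[[k]]$points, s$rows[[k]]$points, tolerance = 1e-9)
    expect_equal(back[[k]]$label, s$rows[[k]]$label)
  }

  # foreign shape types are skipped with a warning
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc$shapes[[length(doc$shapes) + 1]] <-
    list(label = "box", points = list(list(1, 2), list(3, 4)),
         shape_type = "rectangle")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_warning(back2 <- read_labelme(path), "rectangle")
  expect_equal(length(back2), length(s$rows))

  # unsorted linestrips are reordered with a warning
  doc2 <- list(shapes = list(list(label = "r", shape_type = "linestrip",
                                  points = list(list(10, 300), list(12, 100),
                                                list(11, 200)))),
               imageWidth = 640, imageHeight = 360)
  p2 <- tempfile(fileext = ".json")
  jsonlite::write_json(doc2, p2, auto_unbox = TRUE, digits = NA)
  expect_warning(r2 <- read_labelme(p2), "reorder")
  expect_equal(r2[[1]]$points[, 2], c(100, 200, 300))

  # malformed files name the offending key
  p3 <- tempfile(fileext = ".json")
  jsonlite::write_json(list(imageWidth = 10), p3, auto_unbox = TRUE)
  err <- tryCatch(read_labelme(p3), error = function(e) conditionMessage(e))
  expect_match(err, "shapes")
})
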
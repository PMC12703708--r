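# Shared fixtures: tiny synthetic datasets are generated once per test run
# and cached in the session temp directory.

.fixture_env <- new.env()

# small field-scene config used across tests (tiny-profile capture scale)
test_scene_config <- function(seed = 100, ...) {
  scene_config(image_width = 640, image_height = 360, seed = seed, ...)
}

# generate (once) a train/val dataset pair and return the two manifests
fixture_dataset <- function(n_train = 64, n_val = 24) {
  key <- sprintf("ds_%d_%d", n_train, n_val)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  dir <- file.path(tempdir(), paste0("croprows_", key))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man_tr <- generate_dataset(test_scene_config(seed = 100), n_train, "train", dir)
  man_va <- generate_dataset(test_scene_config(seed = 900), n_val, "val", dir)
  out <- list(train = man_tr, val = man_va, dir = dir)
  .fixture_env[[key]] <- out
  out
}

# a straight synthetic sampled row
straight_row <- function(x_bottom, x_top, n_points = 36, height = 160,
                         valid = rep(TRUE, n_points)) {
  ys <- sample_ys(n_points, height)
  xs <- x_bottom + (x_top - x_bottom) * (1 - ys / height)
  sampled_row(ifelse(valid, xs, 0), valid, height)
}

# random row-prediction / ground-truth instances for assignment tests
random_assignment_instance <- function(np, ng, n_points = 5, height = 320,
                                       width = 320) {
  gts <- lapply(seq_len(ng), function(j) {
    xb <- runif(1, 40, width - 40); xt <- xb + runif(1, -60, 60)
    row <- straight_row(xb, xt, n_points, height)
    list(row = row, anchor = croprows:::gt_anchor_from_row(row))
  })
  preds <- lapply(seq_len(np), function(i) {
    th <- runif(1, 0.4, pi - 0.4)
    a <- anchor_line(runif(1, 0, width), height, th, n_points)
    row_prediction(runif(1, 0.05, 0.95), a, rnorm(n_points, 0, 15))
  })
  list(preds = preds, gts = gts)
}
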
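# LabelMe-dialect annotation I/O. Rows are stored as "linestrip" shapes
# (ordered open polylines); other shape types are skipped with a warning.

#' Read row polylines from a LabelMe JSON file
#'
#' @param path path to a LabelMe JSON annotation.
#' @return list of [row_polyline()] objects (one per linestrip shape).
#' @export
read_labelme <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    cr_stop(paste0("malformed LabelMe JSON at ", path, ": ",
                                   conditionMessage(e)), "croprows_parse_error"))
  for (key in c("shapes", "imageWidth", "imageHeight"))
    if (is.null(doc[[key]]))
      cr_stop(paste0("LabelMe file ", path, " is missing required key '", key, "'"),
              "croprows_parse_error")
  w <- doc$imageWidth; h <- doc$imageHeight
  rows <- list()
  for (sh in doc$shapes) {
    if (is.null(sh$shape_type))
      cr_stop(paste0("shape without 'shape_type' in ", path), "croprows_parse_error")
    if (!identical(sh$shape_type, "linestrip")) {
      warning(sprintf("skipping non-linestrip shape of type '%s'", sh$shape_type))
      next
    }
    if (is.null(sh$points))
      cr_stop(paste0("linestrip shape without 'points' in ", path), "croprows_parse_error")
    pts <- do.call(rbind, lapply(sh$points, function(p) c(p[[1]], p[[2]])))
    if (is.unsorted(pts[, 2], strictly = TRUE)) {
      warning("linestrip points not sorted by increasing y; reordering")
      pts <- pts[order(pts[, 2]), , drop = FALSE]
    }
    label <- if (is.null(sh$label)) "row" else sh$label
    rows[[length(rows) + 1]] <- row_polyline(pts, w, h, label)
  }
  rows
}

#' Write row polylines to a LabelMe JSON file
#'
#' @param rows list of [row_polyline()] objects.
#' @param image_meta list with `imagePath`, `imageWidth`, `imageHeight`.
#' @param path output path.
#' @param scores optional numeric vector of per-row detection scores,
#'   stored in each shape's flags.
#' @return invisibly, `path`.
#' @export
write_labelme <- function(rows, image_meta, path, scores = NULL) {
  shapes <- lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    sh <- list(label = r$label,
               points = lapply(seq_len(nrow(r$points)),
                               function(k) as.list(unname(r$points[k, ]))),
               group_id = NULL,
               shape_type = "linestrip",
               flags = if (!is.null(scores)) list(score = scores[i])
                       else structure(list(), names = character(0)))
    sh
  })
  doc <- list(version = "5.2.1",
              flags = structure(list(), names = character(0)),
              shapes = shapes,
              imagePath = image_meta$imagePath,
              imageData = NULL,
              imageHeight = image_meta$imageHeight,
              imageWidth = image_meta$imageWidth)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}
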
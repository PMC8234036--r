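#' Read and write bounding-box annotations
#'
#' Two interchangeable on-disk formats: a JSON list of
#' `{"box": [x0, y0, x1, y1], "label": "bird"}` objects per image, or a
#' CSV with columns `image, x0, y0, x1, y1, label` covering a whole
#' sequence.
#'
#' @param path file path.
#' @param ann annotations data.frame (CSV writer additionally needs an
#'   `image` column or the `image` argument).
#' @param image image identifier for the CSV rows.
#' @return readers return annotation data.frames (the CSV reader keeps the
#'   `image` column); writers return the path invisibly.
#' @export
read_annotations_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (length(raw) == 0L) return(empty_annotations())
  annotations(lapply(raw, function(r) as.numeric(r$box)),
              vapply(raw, function(r) r$label, character(1)))
}

#' @rdname read_annotations_json
#' @export
write_annotations_json <- function(ann, path) {
  recs <- lapply(seq_len(nrow(ann)), function(i) {
    list(box = c(ann$x0[i], ann$y0[i], ann$x1[i], ann$y1[i]),
         label = ann$label[i])
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_annotations_json
#' @export
read_annotations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image", "x0", "y0", "x1", "y1", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation CSV is missing columns: ",
                         paste(miss, collapse = ", "))
  check_label(df$label)
  df
}

#' @rdname read_annotations_json
#' @export
write_annotations_csv <- function(ann, path, image = "frame") {
  df <- cbind(image = if ("image" %in% names(ann)) ann$image else image,
              ann[, c("x0", "y0", "x1", "y1", "label")])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Detection and trigger logs (JSON lines)
#'
#' One JSON object per line. Detection log:
#' `{"frame": i, "boxes": [[x0,y0,x1,y1], ...]}` for every frame.
#' Trigger log: `{"frame": i, "box": [...], "confidence": c}` per event.
#'
#' @param boxes_per_frame list of per-frame box data.frames.
#' @param events trigger events data.frame from [run_trigger()].
#' @param path file path.
#' @return readers return the parsed structures; writers the path,
#'   invisibly.
#' @export
write_detection_log <- function(boxes_per_frame, path) {
  lines <- vapply(seq_along(boxes_per_frame), function(i) {
    b <- boxes_per_frame[[i]]
    jsonlite::toJSON(list(frame = i - 1L,
                          boxes = unname(as.matrix(b[, c("x0", "y0", "x1", "y1")]))),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_detection_log
#' @export
read_detection_log <- function(path) {
  lapply(readLines(path), function(l) {
    r <- jsonlite::fromJSON(l)
    b <- r$boxes
    boxes <- if (length(b) == 0L) empty_boxes() else {
      data.frame(x0 = b[, 1], y0 = b[, 2], x1 = b[, 3], y1 = b[, 4])
    }
    list(frame = r$frame, boxes = boxes)
  })
}

#' @rdname write_detection_log
#' @export
write_trigger_log <- function(events, path) {
  lines <- vapply(seq_len(nrow(events)), function(i) {
    jsonlite::toJSON(list(frame = events$frame[i],
                          box = c(events$x0[i], events$y0[i],
                                  events$x1[i], events$y1[i]),
                          confidence = events$confidence[i]),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a detector configuration from YAML
#'
#' Recognized keys: `threshold`, `accumulator_rate`, `min_area`,
#' `store_dir`; missing keys fall back to the package defaults.
#'
#' @param path YAML file path.
#' @return list with the four keys filled in.
#' @export
read_detector_config <- function(path) {
  y <- yaml::read_yaml(path)
  list(threshold = y$threshold %||% 25,
       accumulator_rate = y$accumulator_rate %||% 0.05,
       min_area = y$min_area %||% 4L,
       store_dir = y$store_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a scene configuration from YAML
#'
#' The YAML mirrors [scene_config()]: top-level scalars plus an `objects`
#' list whose entries have a `kind` and the matching constructor's
#' arguments, and an optional `leaf_quiver` with `regions` (list of
#' `[x0, y0, x1, y1]`), `amplitude` and `period`.
#'
#' @param path YAML file path.
#' @return a [scene_config()].
#' @export
read_scene_config <- function(path) {
  y <- yaml::read_yaml(path)
  objs <- lapply(y$objects %||% list(), function(o) {
    # the YAML 1.1 parser reads the bare keys y/n as booleans; map them back
    names(o)[names(o) == "TRUE"] <- "y"
    names(o)[names(o) == "FALSE"] <- "n"
    kind <- o$kind
    o$kind <- NULL
    ctor <- switch(kind, bird = scene_bird, bug = scene_bug,
                   helicopter = scene_helicopter, flock = scene_flock,
                   stop("unknown scene object kind: ", kind))
    do.call(ctor, o)
  })
  quiver <- if (!is.null(y$leaf_quiver)) {
    list(regions = lapply(y$leaf_quiver$regions, as.numeric),
         amplitude = y$leaf_quiver$amplitude,
         period = y$leaf_quiver$period %||% 1L)
  }
  scene_config(width = y$width %||% 96, height = y$height %||% 96,
               n_frames = y$n_frames %||% 20, seed = y$seed %||% 1,
               background_level = y$background_level %||% 60,
               noise_sd = y$noise_sd %||% 2,
               leaf_quiver = quiver, objects = objs,
               out_of_frame = y$out_of_frame %||% "clip")
}
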
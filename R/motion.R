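#' Differential image between consecutive frames
#'
#' Per-pixel absolute difference of two frames of equal size. The sign of
#' the change carries no information for motion presence, so the detector
#' works with `|current - previous|` throughout.
#'
#' @param current,previous frame matrices of equal dimensions.
#' @return a frame matrix of absolute differences.
#' @examples
#' a <- matrix(50, 4, 4); b <- a; b[2, 2] <- 90
#' difference_frames(b, a)[2, 2]  # 40
#' @export
difference_frames <- function(current, previous) {
  check_same_dims(current, previous)
  abs(current - previous)
}

#' Threshold a differential image to a binary motion mask
#'
#' A pixel is foreground (1) iff its differential intensity strictly exceeds
#' `threshold`. Raising the threshold can therefore never add foreground
#' pixels.
#'
#' @param diff differential image matrix.
#' @param threshold intensity cut in \[0, 255\].
#' @return a 0/1 integer matrix of the same shape.
#' @export
threshold_binary <- function(diff, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 255) {
    stop("threshold must be a single intensity in [0, 255]")
  }
  mask <- diff > threshold
  storage.mode(mask) <- "integer"
  mask
}

#' Accumulated background of differential images
#'
#' The running background is an exponential moving average of past
#' differential images: persistent low-level motion such as quivering
#' grapevine leaves accumulates here frame after frame and is subtracted
#' from each new differential image, while a bird passing once leaves only
#' a trace that decays geometrically.
#'
#' `new_accumulator()` starts from zero; `update_accumulator()` applies
#' `values <- (1 - rate) * values + rate * diff`.
#'
#' @param width,height frame dimensions in pixels.
#' @param rate accumulation weight per frame in \[0, 1\]; 0 freezes the
#'   background, 1 replaces it wholesale each frame. Default 0.05.
#' @return an object of class `background_accumulator` with fields
#'   `values` (matrix), `rate` and `frames_seen`.
#' @export
new_accumulator <- function(width, height, rate = 0.05) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  structure(
    list(values = matrix(0, nrow = height, ncol = width),
         rate = rate, frames_seen = 0L),
    class = "background_accumulator"
  )
}

#' @param acc a `background_accumulator`.
#' @param diff differential image matrix.
#' @rdname new_accumulator
#' @export
update_accumulator <- function(acc, diff) {
  stopifnot(inherits(acc, "background_accumulator"))
  check_same_dims(acc$values, diff, "accumulator and frame")
  acc$values <- (1 - acc$rate) * acc$values + acc$rate * diff
  acc$frames_seen <- acc$frames_seen + 1L
  acc
}

#' Subtract the accumulated background from a differential image
#'
#' Pixelwise `max(diff - background, 0)`: negative evidence is meaningless
#' for a binary detector, so the result is clamped at zero.
#'
#' @param diff differential image matrix.
#' @param acc a `background_accumulator`.
#' @return a frame matrix in \[0, 255\].
#' @export
subtract_background <- function(diff, acc) {
  stopifnot(inherits(acc, "background_accumulator"))
  check_same_dims(diff, acc$values, "frame and accumulator")
  pmax(diff - acc$values, 0)
}

#' Extract object bounding boxes from a binary mask
#'
#' Connected components of the mask under 8-connectivity (diagonal contact
#' joins, which tolerates 1-px gaps in small distant birds) with at least
#' `min_area` foreground pixels each become one tight bounding box. Boxes
#' are 0-based half-open and returned sorted by `(y0, x0)` so detection
#' logs are reproducible.
#'
#' @param mask 0/1 matrix.
#' @param min_area minimum component pixel count, >= 1.
#' @return data.frame with columns `x0, y0, x1, y1` (possibly 0 rows).
#' @export
extract_objects <- function(mask, min_area = 1L) {
  if (min_area < 1) stop("min_area must be >= 1")
  lab <- label_components(mask)
  if (lab$n == 0L) return(empty_boxes())
  out <- empty_boxes()
  for (k in seq_len(lab$n)) {
    idx <- which(lab$labels == k, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    out <- rbind(out, data.frame(
      x0 = min(idx[, 2]) - 1L, y0 = min(idx[, 1]) - 1L,
      x1 = max(idx[, 2]),      y1 = max(idx[, 1])))
  }
  if (nrow(out) > 0L) {
    out <- out[order(out$y0, out$x0), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# 8-connected component labeling by breadth-first flood fill.
# Returns list(labels = integer matrix (0 = background), n = components).
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  fg <- which(mask != 0)
  n <- 0L
  queue <- integer(length(fg))
  for (start in fg) {
    if (labels[start] != 0L) next
    n <- n + 1L
    queue[1] <- start; head <- 1L; tail <- 1L
    labels[start] <- n
    while (head <= tail) {
      p <- queue[head]; head <- head + 1L
      r <- ((p - 1L) %% h) + 1L
      cc <- ((p - 1L) %/% h) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cn <- cc + dc
        if (rr < 1L || rr > h || cn < 1L || cn > w) next
        q <- (cn - 1L) * h + rr
        if (mask[q] != 0 && labels[q] == 0L) {
          labels[q] <- n
          tail <- tail + 1L
          queue[tail] <- q
        }
      }
    }
  }
  list(labels = labels, n = n)
}

#' Motion detector state
#'
#' Bundles the detector configuration (binary threshold, background
#' accumulation rate, minimum component area) with its running state (the
#' previous frame and the accumulated background). Feed frames one at a
#' time with [process_frame()] or a whole sequence with [detect_sequence()].
#'
#' @param threshold binary threshold on the filtered differential image,
#'   default 25 (of 255).
#' @param rate background accumulation rate, default 0.05.
#' @param min_area minimum component area in pixels, default 4.
#' @return an object of class `motion_detector`.
#' @examples
#' det <- motion_detector()
#' frames <- replicate(3, matrix(10, 8, 8), simplify = FALSE)
#' res <- detect_sequence(frames, det)
#' sapply(res$boxes, nrow)  # no motion, no boxes
#' @export
motion_detector <- function(threshold = 25, rate = 0.05, min_area = 4L) {
  structure(
    list(threshold = threshold, rate = rate, min_area = as.integer(min_area),
         previous = NULL, acc = NULL, frame_index = -1L),
    class = "motion_detector"
  )
}

#' @export
print.motion_detector <- function(x, ...) {
  cat("Differential motion detector\n")
  cat(sprintf("  threshold: %g/255, accumulator rate: %g, min area: %d px\n",
              x$threshold, x$rate, x$min_area))
  cat(sprintf("  frames seen: %d\n", x$frame_index + 1L))
  invisible(x)
}

#' Process one frame through the differential pipeline
#'
#' Runs the detection chain in order: difference against the previous
#' frame, subtract the accumulated background, threshold to a binary mask,
#' extract component bounding boxes; the accumulator then absorbs the raw
#' differential image. The very first frame only initializes state and
#' emits no detections (there is no previous image). `store` is TRUE iff at
#' least one box survived, i.e. the frame would be kept as a positive
#' capture.
#'
#' @param detector a [motion_detector()] (carries config and state).
#' @param frame the current frame matrix.
#' @return list with elements `boxes` (data.frame of x0,y0,x1,y1),
#'   `store` (logical) and `detector` (updated state).
#' @export
process_frame <- function(detector, frame) {
  stopifnot(inherits(detector, "motion_detector"))
  frame <- as_frame(frame)
  detector$frame_index <- detector$frame_index + 1L
  if (is.null(detector$previous)) {
    detector$previous <- frame
    detector$acc <- new_accumulator(ncol(frame), nrow(frame), detector$rate)
    return(list(boxes = empty_boxes(), store = FALSE, detector = detector))
  }
  diff <- difference_frames(frame, detector$previous)
  filtered <- subtract_background(diff, detector$acc)
  mask <- threshold_binary(filtered, detector$threshold)
  boxes <- extract_objects(mask, detector$min_area)
  detector$acc <- update_accumulator(detector$acc, diff)
  detector$previous <- frame
  list(boxes = boxes, store = nrow(boxes) > 0L, detector = detector)
}

#' Run the motion detector over a frame sequence
#'
#' @param frames list of frame matrices sharing dimensions.
#' @param detector a [motion_detector()]; a fresh default one if omitted.
#' @return list with `boxes` (per-frame list of box data.frames), `store`
#'   (logical vector) and the final `detector` state.
#' @export
detect_sequence <- function(frames, detector = motion_detector()) {
  boxes <- vector("list", length(frames))
  store <- logical(length(frames))
  for (i in seq_along(frames)) {
    r <- process_frame(detector, frames[[i]])
    boxes[[i]] <- r$boxes
    store[i] <- r$store
    detector <- r$detector
  }
  list(boxes = boxes, store = store, detector = detector)
}
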
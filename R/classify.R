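#' The closed object-class taxonomy
#'
#' The four classes the evaluation operates on: individual birds, insects
#' near the lens ("bug"), flocks (five or more birds flying together — the
#' only class that may trigger the scaring actuator), and helicopters.
#' Finer visual sub-categories (bees vs. flies, soaring vs. retracted
#' wings) collapse onto these four.
#'
#' @export
object_classes <- c("bird", "bug", "flock", "helicopter")

check_label <- function(label) {
  bad <- setdiff(unique(label), object_classes)
  if (length(bad)) {
    stop("unknown object class: ", paste(bad, collapse = ", "),
         " (must be one of ", paste(object_classes, collapse = "/"), ")")
  }
  invisible(label)
}

#' Build a detection or annotation table
#'
#' Detections and annotations are plain data.frames over half-open pixel
#' boxes: annotations carry a ground-truth `label`, detections additionally
#' a `confidence` in \[0, 1\].
#'
#' @param boxes data.frame with columns `x0, y0, x1, y1` or a list of
#'   length-4 vectors.
#' @param label character vector of class labels (recycled).
#' @param confidence numeric vector in \[0, 1\] (recycled), detections only.
#' @return a data.frame with columns `x0, y0, x1, y1, label[, confidence]`.
#' @export
detections <- function(boxes, label, confidence) {
  ann <- annotations(boxes, label)
  if (nrow(ann) == 0L) return(empty_detections())
  if (any(confidence < 0) || any(confidence > 1)) {
    stop("confidence must lie in [0, 1]")
  }
  ann$confidence <- rep_len(confidence, nrow(ann))
  ann
}

#' @rdname detections
#' @export
annotations <- function(boxes, label) {
  if (is.list(boxes) && !is.data.frame(boxes)) {
    boxes <- if (length(boxes) == 0L) empty_boxes() else {
      do.call(rbind, lapply(boxes, function(b) {
        check_box(b)
        data.frame(x0 = b[1], y0 = b[2], x1 = b[3], y1 = b[4])
      }))
    }
  }
  if (nrow(boxes) == 0L) return(empty_annotations())
  for (b in box_rows(boxes)) check_box(b)
  check_label(label)
  out <- boxes[, c("x0", "y0", "x1", "y1"), drop = FALSE]
  out$label <- rep_len(label, nrow(out))
  rownames(out) <- NULL
  out
}

#' Reference heuristic classifier
#'
#' A pluggable stand-in for a trained image classifier, so the rest of the
#' pipeline is testable end to end. It labels candidate boxes by size —
#' tiny blobs are insects buzzing near the lens, very large blobs are
#' helicopters, everything between is a bird — then groups birds into
#' flocks via [group_flocks()]. Confidence grows with blob area (small
#' distant objects are genuinely harder) and, for flocks, with member
#' count. Any function with signature `function(frame, boxes) -> detections`
#' can replace it in [classify_objects()]; this heuristic makes no claim of
#' matching a trained model's accuracy on field imagery.
#'
#' @param bug_max_area area (px) at or below which a blob is called a bug.
#'   Default 2.
#' @param helicopter_min_area area (px) at or above which a blob is called
#'   a helicopter. Default 100.
#' @param proximity flock clustering distance passed to [group_flocks()];
#'   NULL for its adaptive default.
#' @return a classifier function of class `flock_classifier`.
#' @export
heuristic_classifier <- function(bug_max_area = 2, helicopter_min_area = 100,
                                 proximity = NULL) {
  f <- function(frame, boxes) {
    if (nrow(boxes) == 0L) return(empty_detections())
    areas <- (boxes$x1 - boxes$x0) * (boxes$y1 - boxes$y0)
    label <- ifelse(areas <= bug_max_area, "bug",
                    ifelse(areas >= helicopter_min_area, "helicopter", "bird"))
    conf <- ifelse(label == "bug", 0.5,
                   ifelse(label == "helicopter",
                          pmin(0.5 + areas / 400, 0.99),
                          pmin(0.5 + areas / 40, 0.95)))
    dets <- detections(boxes, label, conf)
    group_flocks(dets, proximity = proximity)
  }
  structure(f, class = c("flock_classifier", "function"))
}

#' Classify candidate boxes in a frame
#'
#' The classifier contract: takes a frame and the candidate boxes the
#' motion detector produced, returns labeled detections with confidences.
#' Implementations are interchangeable — the bundled
#' [heuristic_classifier()] or any adapter around an external model.
#'
#' @param frame frame matrix.
#' @param boxes data.frame of candidate boxes (`x0, y0, x1, y1`).
#' @param classifier a `function(frame, boxes)` returning detections.
#' @return a detections data.frame.
#' @export
classify_objects <- function(frame, boxes,
                             classifier = heuristic_classifier()) {
  frame <- as_frame(frame)
  if (nrow(boxes) > 0L) {
    inside <- boxes$x0 >= 0 & boxes$y0 >= 0 &
      boxes$x1 <= ncol(frame) & boxes$y1 <= nrow(frame)
    if (!all(inside)) {
      stop(sprintf("box %d lies outside the %dx%d frame",
                   which(!inside)[1], ncol(frame), nrow(frame)))
    }
  }
  classifier(frame, boxes)
}

#' Group nearby bird detections into flocks
#'
#' A flock is five or more birds flying together. "Together" is
#' operationalized as single-linkage clustering of bird box centers cut at
#' `proximity`: every cluster of >= 5 birds is replaced by one flock
#' detection whose box is the cluster's bounding hull and whose confidence
#' is the mean member confidence; clusters of four or fewer pass through
#' unchanged. Non-bird detections are never touched.
#'
#' @param dets detections data.frame.
#' @param proximity maximum center-to-center gap (px) for single linkage;
#'   default is 4x the median bird-box diagonal of the input.
#' @return a detections data.frame, sorted by `(y0, x0, label)`.
#' @export
group_flocks <- function(dets, proximity = NULL) {
  birds <- dets[dets$label == "bird", , drop = FALSE]
  rest <- dets[dets$label != "bird", , drop = FALSE]
  if (nrow(birds) == 0L) return(sort_detections(dets))
  if (is.null(proximity)) {
    diag_len <- sqrt((birds$x1 - birds$x0)^2 + (birds$y1 - birds$y0)^2)
    proximity <- 4 * stats::median(diag_len)
  }
  if (proximity <= 0) stop("proximity must be positive")
  cl <- if (nrow(birds) == 1L) 1L else {
    cx <- (birds$x0 + birds$x1) / 2
    cy <- (birds$y0 + birds$y1) / 2
    hc <- stats::hclust(stats::dist(cbind(cx, cy)), method = "single")
    stats::cutree(hc, h = proximity)
  }
  out <- rest
  for (k in unique(cl)) {
    members <- birds[cl == k, , drop = FALSE]
    if (nrow(members) >= 5L) {
      out <- rbind(out, data.frame(
        x0 = min(members$x0), y0 = min(members$y0),
        x1 = max(members$x1), y1 = max(members$y1),
        label = "flock", confidence = mean(members$confidence)))
    } else {
      out <- rbind(out, members)
    }
  }
  sort_detections(out)
}

sort_detections <- function(dets) {
  if (nrow(dets) == 0L) return(dets)
  dets <- dets[order(dets$y0, dets$x0, dets$label), , drop = FALSE]
  rownames(dets) <- NULL
  dets
}
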
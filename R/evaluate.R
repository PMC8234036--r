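#' Intersection over Union (Jaccard index) of two boxes
#'
#' Overlap area divided by union area of two half-open pixel rectangles:
#' 1 for identical boxes, 0 for disjoint ones, symmetric in its arguments.
#' A detection is considered valid only when its IoU with a ground-truth
#' box reaches the matching threshold (50% by default).
#'
#' @param a,b boxes as `c(x0, y0, x1, y1)`.
#' @return IoU in \[0, 1\].
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 1, 3, 3))  # 1/7
#' @export
iou <- function(a, b) {
  check_box(a); check_box(b)
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (box_area(a) + box_area(b) - inter)
}

# IoU matrix detections x annotations (either may have 0 rows), vectorized
iou_matrix <- function(det, ann) {
  nd <- nrow(det); na <- nrow(ann)
  if (nd == 0L || na == 0L) return(matrix(0, nd, na))
  iw <- outer(det$x1, ann$x1, pmin) - outer(det$x0, ann$x0, pmax)
  ih <- outer(det$y1, ann$y1, pmin) - outer(det$y0, ann$y0, pmax)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  da <- (det$x1 - det$x0) * (det$y1 - det$y0)
  aa <- (ann$x1 - ann$x0) * (ann$y1 - ann$y0)
  inter / (outer(da, aa, "+") - inter)
}

#' Match detections to ground-truth annotations
#'
#' One-to-one greedy assignment in descending detection confidence: each
#' detection in turn takes the free annotation of highest IoU, provided
#' that IoU reaches `iou_threshold` (ties go to the lower annotation
#' index). Class labels are deliberately ignored at match time — a
#' cross-class match is the raw material of the confusion matrix, counting
#' as FP for the predicted class and FN for the true one.
#'
#' @param det detections data.frame.
#' @param ann annotations data.frame.
#' @param iou_threshold minimum overlap in (0, 1\]; default 0.5 ("at least
#'   50% overlap with the ground-truth template").
#' @return an object of class `match_result`: `pairs` (data.frame
#'   `detection, annotation, iou`, 1-based row indices),
#'   `unmatched_detections`, `unmatched_annotations`.
#' @export
match_detections <- function(det, ann, iou_threshold = 0.5) {
  if (iou_threshold <= 0 || iou_threshold > 1) {
    stop("iou_threshold must lie in (0, 1]")
  }
  taken <- logical(nrow(ann))
  p_det <- integer(0); p_ann <- integer(0); p_iou <- numeric(0)
  if (nrow(det) > 0L && nrow(ann) > 0L) {
    m <- iou_matrix(det, ann)
    ord <- order(-det$confidence, seq_len(nrow(det)))
    for (i in ord) {
      free <- which(!taken & m[i, ] >= iou_threshold)
      if (length(free) == 0L) next
      j <- free[which.max(m[i, free])]  # which.max -> lowest index on ties
      taken[j] <- TRUE
      p_det <- c(p_det, i); p_ann <- c(p_ann, j); p_iou <- c(p_iou, m[i, j])
    }
  }
  pairs <- data.frame(detection = p_det, annotation = p_ann, iou = p_iou)
  structure(
    list(pairs = pairs,
         unmatched_detections = setdiff(seq_len(nrow(det)), pairs$detection),
         unmatched_annotations = which(!taken)),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("Detection matching: %d pairs, %d unmatched detections, %d missed annotations\n",
              nrow(x$pairs), length(x$unmatched_detections),
              length(x$unmatched_annotations)))
  invisible(x)
}

#' Per-class detection tallies
#'
#' For each class c: TP = matched pairs where both labels are c; FN =
#' annotations of c left unmatched or matched under another label; FP =
#' detections labeled c that are unmatched or matched to an annotation of
#' a different class. TN is fixed at 0 — object detection offers no
#' natural true-negative count — which is exactly the convention under
#' which the error-rate formula reproduces published per-class tables.
#'
#' @param match a `match_result` from [match_detections()].
#' @param det,ann the detections/annotations that produced it.
#' @param classes class labels to tabulate; defaults to [object_classes].
#' @return data.frame with columns `class, gt, tp, fp, fn, tn`.
#' @export
tally_counts <- function(match, det, ann, classes = object_classes) {
  dl <- if (nrow(match$pairs)) det$label[match$pairs$detection] else character(0)
  al <- if (nrow(match$pairs)) ann$label[match$pairs$annotation] else character(0)
  out <- lapply(classes, function(cl) {
    gt <- sum(ann$label == cl)
    tp <- sum(dl == cl & al == cl)
    fn <- sum(ann$label[match$unmatched_annotations] == cl) +
      sum(al == cl & dl != cl)
    fp <- sum(det$label[match$unmatched_detections] == cl) +
      sum(dl == cl & al != cl)
    data.frame(class = cl, gt = gt, tp = tp, fp = fp, fn = fn, tn = 0L)
  })
  do.call(rbind, out)
}

check_counts <- function(c) {
  need <- c("tp", "fp", "fn", "tn")
  miss <- setdiff(need, names(c))
  if (length(miss)) stop("counts are missing: ", paste(miss, collapse = ", "))
  invisible(c)
}

#' Detection quality metrics for one class
#'
#' All four metrics are percentages rounded half-up to one decimal place.
#' `precision = 100 * TP / (TP + FP)`;
#' `recall    = 100 * TP / (TP + FN)` (sensitivity);
#' `f1_score  = 100 * 2 TP / (2 TP + FP + FN)` (harmonic mean of the two);
#' `error_rate = 100 * (FP + FN) / (FP + FN + TP + TN)` with TN = 0 by
#' convention. Each errors out when its denominator is zero (the metric is
#' undefined, e.g. precision for a class never predicted).
#'
#' @param counts a list or one-row data.frame with `tp, fp, fn, tn`.
#' @return percentage, one decimal.
#' @examples
#' precision(list(tp = 33, fp = 0, fn = 2, tn = 0))   # 100.0
#' recall(list(tp = 33, fp = 0, fn = 2, tn = 0))      # 94.3
#' f1_score(list(tp = 33, fp = 0, fn = 2, tn = 0))    # 97.1
#' error_rate(list(tp = 33, fp = 0, fn = 2, tn = 0))  # 5.7
#' @export
precision <- function(counts) {
  check_counts(counts)
  d <- counts$tp + counts$fp
  if (d == 0) stop("precision undefined: no detections of this class (tp + fp = 0)")
  round_half_up(100 * counts$tp / d)
}

#' @rdname precision
#' @export
recall <- function(counts) {
  check_counts(counts)
  d <- counts$tp + counts$fn
  if (d == 0) stop("recall undefined: no ground-truth objects of this class (tp + fn = 0)")
  round_half_up(100 * counts$tp / d)
}

#' @rdname precision
#' @export
f1_score <- function(counts) {
  check_counts(counts)
  d <- 2 * counts$tp + counts$fp + counts$fn
  if (d == 0) stop("F1 undefined: 2 tp + fp + fn = 0")
  round_half_up(100 * 2 * counts$tp / d)
}

#' @rdname precision
#' @export
error_rate <- function(counts) {
  check_counts(counts)
  d <- counts$fp + counts$fn + counts$tp + counts$tn
  if (d == 0) stop("error rate undefined: fp + fn + tp + tn = 0")
  round_half_up(100 * (counts$fp + counts$fn) / d)
}

#' Multi-class confusion matrix with out-of-class false positives
#'
#' Cell (g, p) counts annotations of true class g matched by detections of
#' predicted class p; detections that matched no annotation at all are
#' tallied separately per predicted class as out-of-class false positives
#' (objects outside every ground-truth subclass).
#'
#' @inheritParams tally_counts
#' @return object of class `confusion_matrix`: `counts` (classes x
#'   classes, rows = ground truth, cols = predicted) and `out_of_class_fp`
#'   (named vector per predicted class).
#' @export
confusion_matrix <- function(match, det, ann, classes = object_classes) {
  counts <- matrix(0L, length(classes), length(classes),
                   dimnames = list(truth = classes, predicted = classes))
  if (nrow(match$pairs)) {
    for (r in seq_len(nrow(match$pairs))) {
      g <- ann$label[match$pairs$annotation[r]]
      p <- det$label[match$pairs$detection[r]]
      counts[g, p] <- counts[g, p] + 1L
    }
  }
  ooc <- stats::setNames(integer(length(classes)), classes)
  for (i in match$unmatched_detections) {
    ooc[det$label[i]] <- ooc[det$label[i]] + 1L
  }
  structure(list(counts = counts, out_of_class_fp = ooc),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = ground truth, cols = predicted):\n")
  print(x$counts)
  cat("Out-of-class false positives per predicted class:\n")
  print(x$out_of_class_fp)
  invisible(x)
}

#' Evaluate detections against ground truth
#'
#' The full scoring pipeline: IoU matching at `iou_threshold`, per-class
#' tallies, the four metrics per class (NA where a metric's denominator is
#' zero), and the confusion matrix.
#'
#' @inheritParams match_detections
#' @param classes class labels to report; defaults to [object_classes].
#' @return object of class `detection_evaluation` with fields `counts`
#'   (class, gt, tp, fp, fn, tn), `metrics` (class, precision, recall, f1,
#'   error_rate), `confusion` and `match`.
#' @export
evaluate_detections <- function(det, ann, iou_threshold = 0.5,
                                classes = object_classes) {
  match <- match_detections(det, ann, iou_threshold)
  counts <- tally_counts(match, det, ann, classes)
  safe <- function(f, row) tryCatch(f(row), error = function(e) NA_real_)
  metrics <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    row <- counts[i, ]
    data.frame(class = row$class,
               precision = safe(precision, row),
               recall = safe(recall, row),
               f1 = safe(f1_score, row),
               error_rate = safe(error_rate, row))
  }))
  structure(
    list(counts = counts, metrics = metrics,
         confusion = confusion_matrix(match, det, ann, classes),
         match = match),
    class = "detection_evaluation"
  )
}

#' @export
print.detection_evaluation <- function(x, ...) {
  cat("Detection evaluation\n\nPer-class counts:\n")
  print(x$counts, row.names = FALSE)
  cat("\nPer-class metrics (%):\n")
  print(x$metrics, row.names = FALSE)
  cat("\n")
  print(x$confusion)
  invisible(x)
}

#' Write the evaluation report as CSV files
#'
#' Writes `<stem>_metrics.csv` (class, gt, tp, fp, fn, precision, recall,
#' f1, error_rate) and `<stem>_confusion.csv` (ground-truth rows x
#' predicted columns plus an `out_of_class_fp` row).
#'
#' @param eval a `detection_evaluation`.
#' @param stem output path stem (no extension).
#' @return the two paths, invisibly.
#' @export
write_evaluation_report <- function(eval, stem) {
  stopifnot(inherits(eval, "detection_evaluation"))
  tab <- merge(eval$counts[, c("class", "gt", "tp", "fp", "fn")],
               eval$metrics, by = "class", sort = FALSE)
  p1 <- paste0(stem, "_metrics.csv")
  utils::write.csv(tab, p1, row.names = FALSE)
  conf <- as.data.frame(eval$confusion$counts)
  conf <- cbind(truth = rownames(eval$confusion$counts),
                as.data.frame.matrix(eval$confusion$counts))
  conf <- rbind(conf, c(truth = "out_of_class_fp",
                        as.list(eval$confusion$out_of_class_fp)))
  p2 <- paste0(stem, "_confusion.csv")
  utils::write.csv(conf, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
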
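# Independent reference implementations used as oracles. Everything here is
# deliberately naive — double loops, no vectorization, no calls into the
# package's own pipeline internals — so agreement is meaningful.

# per-pixel absolute difference
naive_diff <- function(a, b) {
  out <- matrix(0, nrow(a), ncol(a))
  for (r in seq_len(nrow(a))) for (c in seq_len(ncol(a))) {
    out[r, c] <- abs(a[r, c] - b[r, c])
  }
  out
}

# full detector chain on a sequence: diff -> subtract accumulated background
# (EMA of past diffs) -> threshold -> 8-connected components >= min_area
naive_detect_sequence <- function(frames, threshold = 25, rate = 0.05,
                                  min_area = 4) {
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  acc <- matrix(0, h, w)
  boxes <- vector("list", length(frames))
  boxes[[1]] <- data.frame(x0 = integer(0), y0 = integer(0),
                           x1 = integer(0), y1 = integer(0))
  for (f in seq_along(frames)[-1]) {
    d <- naive_diff(frames[[f]], frames[[f - 1]])
    mask <- matrix(0L, h, w)
    for (r in seq_len(h)) for (c in seq_len(w)) {
      v <- d[r, c] - acc[r, c]
      if (v < 0) v <- 0
      if (v > threshold) mask[r, c] <- 1L
    }
    for (r in seq_len(h)) for (c in seq_len(w)) {
      acc[r, c] <- (1 - rate) * acc[r, c] + rate * d[r, c]
    }
    boxes[[f]] <- naive_components(mask, min_area)
  }
  boxes
}

# component labeling by iterated min-label propagation (not flood fill)
naive_components <- function(mask, min_area = 1) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  lab[mask == 1L] <- seq_len(sum(mask))
  repeat {
    changed <- FALSE
    for (r in seq_len(h)) for (c in seq_len(w)) {
      if (mask[r, c] == 0L) next
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > h || cc < 1 || cc > w) next
        if (mask[rr, cc] == 1L && lab[rr, cc] < lab[r, c]) {
          lab[r, c] <- lab[rr, cc]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- data.frame(x0 = integer(0), y0 = integer(0),
                    x1 = integer(0), y1 = integer(0))
  for (k in unique(lab[lab > 0L])) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    out <- rbind(out, data.frame(x0 = min(idx[, 2]) - 1L, y0 = min(idx[, 1]) - 1L,
                                 x1 = max(idx[, 2]), y1 = max(idx[, 1])))
  }
  out <- out[order(out$y0, out$x0), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# brute-force single linkage: merge any two clusters holding a pair of
# points closer than h, until no such pair remains
naive_single_linkage <- function(xy, h) {
  n <- nrow(xy)
  cl <- seq_len(n)
  repeat {
    merged <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (cl[i] != cl[j] &&
          sqrt(sum((xy[i, ] - xy[j, ])^2)) <= h) {
        cl[cl == cl[j]] <- cl[i]
        merged <- TRUE
      }
    }
    if (!merged) break
  }
  match(cl, unique(cl))
}

# frame with one or more solid square blobs on a flat background
blob_frame <- function(w, h, level, blobs, intensity = 200) {
  px <- matrix(level, h, w)
  for (b in blobs) {  # b = c(x, y, size), 0-based top-left
    px[(b[2] + 1):(b[2] + b[3]), (b[1] + 1):(b[1] + b[3])] <- intensity
  }
  px
}

# the printed per-class tallies and cross-class confusion used throughout:
# bird/bug/flock/helicopter GT-TP-FP-FN plus matched-pair label combinations
published_counts <- function() {
  data.frame(class = object_classes,
             gt = c(898, 71, 35, 4), tp = c(749, 48, 33, 4),
             fp = c(145, 24, 0, 0), fn = c(149, 23, 2, 0))
}

published_confusion <- function() {
  matrix(c(749, 1, 0, 0,
           3, 48, 0, 0,
           1, 0, 33, 0,
           0, 0, 0, 4),
         4, 4, byrow = TRUE,
         dimnames = list(object_classes, object_classes))
}
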
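#' Synthetic vineyard scene objects
#'
#' Object specs for [generate_scene()]. Positions are the blob's top-left
#' pixel at frame 0; velocities are in px/frame. Default blob sizes echo
#' how the four classes appear to a vineyard camera: birds a few pixels
#' across, near-lens insects one or two pixels moving erratically,
#' helicopters large and slow, flocks a coherent cluster of five or more
#' bird blobs sharing a velocity with small per-member jitter.
#'
#' @param x,y start position (px, 0-based).
#' @param vx,vy velocity (px/frame).
#' @param size blob side length (px).
#' @param intensity blob intensity in \[0, 255\].
#' @param step_sd bug random-walk step standard deviation (px/frame).
#' @param members flock member count, >= 5.
#' @param spread flock member scatter radius (px).
#' @param jitter per-frame member position jitter sd (px).
#' @return an object spec list of class `scene_object`.
#' @export
scene_bird <- function(x, y, vx = 0, vy = 0, size = 3, intensity = 200) {
  structure(list(kind = "bird", x = x, y = y, vx = vx, vy = vy,
                 size = size, intensity = intensity),
            class = "scene_object")
}

#' @rdname scene_bird
#' @export
scene_bug <- function(x, y, size = 1, intensity = 200, step_sd = 3) {
  structure(list(kind = "bug", x = x, y = y, vx = 0, vy = 0,
                 size = size, intensity = intensity, step_sd = step_sd),
            class = "scene_object")
}

#' @rdname scene_bird
#' @export
scene_helicopter <- function(x, y, vx = 1, vy = 0, size = 16,
                             intensity = 180) {
  structure(list(kind = "helicopter", x = x, y = y, vx = vx, vy = vy,
                 size = size, intensity = intensity),
            class = "scene_object")
}

#' @rdname scene_bird
#' @export
scene_flock <- function(x, y, vx = 2, vy = 0, members = 6, spread = 8,
                        size = 3, jitter = 0.3, intensity = 220) {
  if (members < 5) stop("a flock has at least five members")
  structure(list(kind = "flock", x = x, y = y, vx = vx, vy = vy,
                 members = as.integer(members), spread = spread,
                 size = size, jitter = jitter, intensity = intensity),
            class = "scene_object")
}

#' Synthetic scene configuration
#'
#' @param width,height frame size (px).
#' @param n_frames sequence length.
#' @param seed RNG seed; the seed fully determines the rendered frames.
#' @param background_level flat background intensity.
#' @param noise_sd additive Gaussian sensor noise sd (intensity levels).
#' @param leaf_quiver NULL, or `list(regions = <list of boxes>, amplitude,
#'   period)`: each region's intensity alternates by +/- amplitude every
#'   `period` frames, emulating quivering grapevine leaves.
#' @param objects list of [scene_bird()]/[scene_bug()]/
#'   [scene_helicopter()]/[scene_flock()] specs.
#' @param out_of_frame `"clip"` (default) clips boxes of objects partly
#'   outside the frame; `"drop"` drops their annotation instead. Objects
#'   fully outside are always dropped.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(width = 96, height = 96, n_frames = 20, seed = 1,
                         background_level = 60, noise_sd = 2,
                         leaf_quiver = NULL, objects = list(),
                         out_of_frame = c("clip", "drop")) {
  out_of_frame <- match.arg(out_of_frame)
  for (ob in objects) {
    stopifnot(inherits(ob, "scene_object"))
    if (ob$x < 0 || ob$y < 0 || ob$x >= width || ob$y >= height) {
      stop("objects must start within the frame")
    }
  }
  structure(list(width = width, height = height, n_frames = n_frames,
                 seed = seed, background_level = background_level,
                 noise_sd = noise_sd, leaf_quiver = leaf_quiver,
                 objects = objects, out_of_frame = out_of_frame),
            class = "scene_config")
}

#' Generate a synthetic frame sequence with ground truth
#'
#' Renders `n_frames` grayscale frames: flat background plus optional
#' sensor noise and leaf-quiver flicker, with the configured objects
#' propagated linearly (bugs take random-walk steps; flock members share
#' the flock velocity plus small jitter). Every frame comes with tight
#' ground-truth boxes: one per bird/bug/helicopter, and one hull box per
#' flock covering all its members. Identical seeds give byte-identical
#' output; the caller's RNG state is left untouched.
#'
#' @param config a [scene_config()].
#' @return list with `frames` (list of matrices) and `annotations` (list
#'   of annotation data.frames, one per frame).
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  w <- config$width; h <- config$height; nf <- config$n_frames
  # pre-sample trajectories so rendering order cannot disturb determinism
  trajs <- lapply(config$objects, function(ob) {
    t <- seq_len(nf) - 1
    if (ob$kind == "bug") {
      steps_x <- c(ob$x, ob$x + cumsum(stats::rnorm(nf - 1, 0, ob$step_sd)))
      steps_y <- c(ob$y, ob$y + cumsum(stats::rnorm(nf - 1, 0, ob$step_sd)))
      list(kind = "bug", size = ob$size, intensity = ob$intensity,
           x = steps_x, y = steps_y)
    } else if (ob$kind == "flock") {
      # ring formation: members stay resolvable as distinct blobs, which is
      # what makes ">= 5 birds flying together" observable in the image
      ang <- 2 * pi * (seq_len(ob$members) - 1) / ob$members
      offx <- ob$spread * cos(ang); offy <- ob$spread * sin(ang)
      jx <- matrix(stats::rnorm(ob$members * nf, 0, ob$jitter), ob$members)
      jy <- matrix(stats::rnorm(ob$members * nf, 0, ob$jitter), ob$members)
      mx <- outer(offx, ob$x + ob$vx * t, "+") + jx
      my <- outer(offy, ob$y + ob$vy * t, "+") + jy
      list(kind = "flock", size = ob$size, intensity = ob$intensity,
           mx = mx, my = my)
    } else {
      list(kind = ob$kind, size = ob$size, intensity = ob$intensity,
           x = ob$x + ob$vx * t, y = ob$y + ob$vy * t)
    }
  })
  noise <- if (config$noise_sd > 0) {
    lapply(seq_len(nf), function(i) {
      matrix(stats::rnorm(w * h, 0, config$noise_sd), h, w)
    })
  }

  draw_blob <- function(px, x, y, size, intensity) {
    x <- round(x); y <- round(y)
    cs <- max(x, 0):min(x + size - 1, w - 1)
    rs <- max(y, 0):min(y + size - 1, h - 1)
    if (length(cs) == 0 || length(rs) == 0 ||
        x + size <= 0 || y + size <= 0 || x >= w || y >= h) {
      return(px)
    }
    px[rs + 1, cs + 1] <- intensity
    px
  }
  blob_box <- function(x, y, size) {
    c(round(x), round(y), round(x) + size, round(y) + size)
  }
  # clip to frame; NULL when fully outside or (policy drop) partly outside
  admit_box <- function(box) {
    clipped <- c(max(box[1], 0), max(box[2], 0), min(box[3], w), min(box[4], h))
    if (clipped[1] >= clipped[3] || clipped[2] >= clipped[4]) return(NULL)
    if (config$out_of_frame == "drop" && !identical(clipped, box)) return(NULL)
    clipped
  }

  frames <- vector("list", nf)
  anns <- vector("list", nf)
  for (f in seq_len(nf)) {
    px <- matrix(config$background_level, h, w)
    if (!is.null(noise)) px <- px + noise[[f]]
    if (!is.null(config$leaf_quiver)) {
      q <- config$leaf_quiver
      sgn <- if ((((f - 1) %/% q$period) %% 2) == 0) 1 else -1
      for (rg in q$regions) {
        px[(rg[2] + 1):rg[4], (rg[1] + 1):rg[3]] <-
          px[(rg[2] + 1):rg[4], (rg[1] + 1):rg[3]] + sgn * q$amplitude
      }
    }
    boxes <- list(); labels <- character(0)
    for (tr in trajs) {
      if (tr$kind == "flock") {
        hull <- NULL
        for (m in seq_len(nrow(tr$mx))) {
          px <- draw_blob(px, tr$mx[m, f], tr$my[m, f], tr$size, tr$intensity)
          b <- blob_box(tr$mx[m, f], tr$my[m, f], tr$size)
          hull <- if (is.null(hull)) b else {
            c(min(hull[1], b[1]), min(hull[2], b[2]),
              max(hull[3], b[3]), max(hull[4], b[4]))
          }
        }
        b <- admit_box(hull)
        if (!is.null(b)) { boxes[[length(boxes) + 1]] <- b
                           labels <- c(labels, "flock") }
      } else {
        px <- draw_blob(px, tr$x[f], tr$y[f], tr$size, tr$intensity)
        b <- admit_box(blob_box(tr$x[f], tr$y[f], tr$size))
        if (!is.null(b)) { boxes[[length(boxes) + 1]] <- b
                           labels <- c(labels, tr$kind) }
      }
    }
    frames[[f]] <- pmin(pmax(px, 0), 255)
    anns[[f]] <- annotations(boxes, if (length(labels)) labels else character(0))
  }
  list(frames = frames, annotations = anns)
}

#' The benign reference scene
#'
#' A high-contrast 160x120, 20-frame sequence holding three well-separated
#' six-member flocks crossing the view at 2 px/frame — the standard
#' configuration for the end-to-end self-consistency check of detector,
#' classifier, grouping and evaluation.
#'
#' @param seed RNG seed.
#' @return a [scene_config()].
#' @export
reference_scene <- function(seed = 42) {
  scene_config(
    width = 160, height = 120, n_frames = 20, seed = seed,
    background_level = 60, noise_sd = 2,
    objects = list(
      scene_flock(x = 20, y = 14, vx = 2, vy = 0),
      scene_flock(x = 24, y = 58, vx = 2, vy = 0),
      scene_flock(x = 18, y = 100, vx = 2, vy = 0)
    )
  )
}

#' Build a detection/annotation fixture realizing given tallies
#'
#' Constructs abstract detections and annotations — disjoint unit boxes on
#' a grid, coincident where a match is wanted — such that matching at IoU
#' 0.5 reproduces the requested per-class counts and confusion matrix
#' exactly. This turns a published results table into an executable input
#' for the evaluation pipeline.
#'
#' @param counts data.frame with columns `class, gt, tp, fp, fn`.
#' @param confusion optional classes x classes matrix (rows = truth, cols
#'   = predicted) of matched-pair label combinations; default is
#'   `diag(tp)`, i.e. no cross-class confusion.
#' @return list with `detections` and `annotations` data.frames.
#' @export
make_fixture_from_counts <- function(counts, confusion = NULL) {
  cls <- counts$class
  if (is.null(confusion)) {
    confusion <- diag(counts$tp, nrow = length(cls))
    dimnames(confusion) <- list(cls, cls)
  }
  confusion <- confusion[cls, cls, drop = FALSE]
  if (any(counts$tp + counts$fn != counts$gt)) {
    stop("inconsistent counts: tp + fn must equal gt for every class")
  }
  if (any(diag(confusion) != counts$tp)) {
    stop("inconsistent counts: confusion diagonal must equal tp")
  }
  if (any(rowSums(confusion) > counts$gt)) {
    stop("inconsistent counts: confusion row sums exceed gt")
  }
  cross_fp <- colSums(confusion) - diag(confusion)
  if (any(cross_fp > counts$fp)) {
    stop("inconsistent counts: cross-class matches exceed fp")
  }

  k <- 0L
  next_box <- function() {
    k <<- k + 1L
    c(2 * (k - 1L), 0, 2 * (k - 1L) + 1, 1)
  }
  ann_boxes <- list(); ann_labels <- character(0)
  det_boxes <- list(); det_labels <- character(0); det_conf <- numeric(0)
  add_ann <- function(b, lab) {
    ann_boxes[[length(ann_boxes) + 1L]] <<- b
    ann_labels <<- c(ann_labels, lab)
  }
  add_det <- function(b, lab, conf) {
    det_boxes[[length(det_boxes) + 1L]] <<- b
    det_labels <<- c(det_labels, lab)
    det_conf <<- c(det_conf, conf)
  }
  for (gi in seq_along(cls)) {
    for (pi in seq_along(cls)) {
      n <- confusion[gi, pi]
      for (i in seq_len(n)) {
        b <- next_box()
        add_ann(b, cls[gi])
        add_det(b, cls[pi], 0.9)
      }
    }
    for (i in seq_len(counts$gt[gi] - sum(confusion[gi, ]))) {
      add_ann(next_box(), cls[gi])   # missed object: annotation alone
    }
  }
  for (pi in seq_along(cls)) {
    for (i in seq_len(counts$fp[pi] - cross_fp[pi])) {
      add_det(next_box(), cls[pi], 0.8)  # out-of-class false positive
    }
  }
  list(detections = detections(det_boxes, det_labels, det_conf),
       annotations = annotations(ann_boxes, ann_labels))
}
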
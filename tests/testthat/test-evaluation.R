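test_that("IoU is symmetric, bounded, and exact on pixel counts", {
  a <- c(0, 0, 2, 2)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, c(5, 5, 7, 7)), 0)
  # overlap 1 px, union 7 px
  expect_equal(iou(a, c(1, 1, 3, 3)), 1 / 7)
  expect_equal(iou(c(1, 1, 3, 3), a), 1 / 7)
  # boxes merely touching share no area
  expect_equal(iou(a, c(2, 0, 4, 2)), 0)
})

test_that("matching is greedy by confidence, one-to-one, label-blind", {
  empty <- match_detections(detections(list(), character(0), numeric(0)),
                            annotations(list(), character(0)))
  expect_equal(nrow(empty$pairs), 0L)

  det <- detections(list(c(0, 0, 4, 4)), "bird", 0.9)
  ann <- annotations(list(c(0, 0, 4, 4)), "bird")
  m <- match_detections(det, ann)
  expect_equal(m$pairs$iou, 1)

  # two detections over one annotation: the confident one wins
  det2 <- detections(list(c(0, 0, 4, 4), c(0, 0, 4, 3)), "bird", c(0.4, 0.9))
  m2 <- match_detections(det2, ann)
  expect_equal(m2$pairs$detection, 2L)
  expect_equal(m2$unmatched_detections, 1L)

  # a cross-class overlap still matches (it will be scored as confusion)
  det3 <- detections(list(c(0, 0, 4, 4)), "bug", 0.8)
  m3 <- match_detections(det3, ann)
  expect_equal(nrow(m3$pairs), 1L)

  # below-threshold overlap does not match
  det4 <- detections(list(c(0, 0, 4, 2)), "bird", 0.8)  # IoU 0.5 exactly
  expect_equal(nrow(match_detections(det4, ann, 0.5)$pairs), 1L)
  det5 <- detections(list(c(0, 0, 4, 1)), "bird", 0.8)  # IoU 0.25
  expect_equal(nrow(match_detections(det5, ann, 0.5)$pairs), 0L)

  expect_error(match_detections(det, ann, 0), "\\(0, 1\\]")
})

test_that("matching is stable under permutation given distinct confidences", {
  set.seed(33)
  for (trial in 1:20) {
    n <- sample(3:8, 1)
    ann <- annotations(lapply(seq_len(n), function(i) {
      x <- 6 * i; c(x, 0, x + 4, 4)
    }), sample(object_classes, n, replace = TRUE))
    det <- detections(lapply(seq_len(n), function(i) {
      x <- 6 * i + sample(-1:1, 1); c(x, 0, x + 4, 4)
    }), sample(object_classes, n, replace = TRUE),
    sample(seq(0.3, 0.95, by = 0.01), n))
    m1 <- match_detections(det, ann)
    perm <- sample(n)
    m2 <- match_detections(det[perm, ], ann)
    got <- m2$pairs
    got$detection <- perm[got$detection]
    expect_equal(m1$pairs[order(m1$pairs$detection), c("detection", "annotation")],
                 got[order(got$detection), c("detection", "annotation")],
                 ignore_attr = TRUE)
  }
})

test_that("per-class tallies follow the FP/FN conventions", {
  # perfect detector: fp = fn = 0, tp = gt
  ann <- annotations(lapply(1:6, function(i) c(3 * i, 0, 3 * i + 2, 2)),
                     c("bird", "bird", "bug", "flock", "flock", "helicopter"))
  det <- detections(lapply(1:6, function(i) c(3 * i, 0, 3 * i + 2, 2)),
                    c("bird", "bird", "bug", "flock", "flock", "helicopter"),
                    0.9)
  tc <- tally_counts(match_detections(det, ann), det, ann)
  expect_equal(tc$fp, rep(0L, 4))
  expect_equal(tc$fn, rep(0L, 4))
  expect_equal(tc$tp, tc$gt)

  # 35 flock GT: 33 matched flock-flock, 1 matched by a bird-labeled
  # detection, 1 unmatched -> tp 33, fn 2, fp 0
  counts <- data.frame(class = object_classes,
                       gt = c(0, 0, 35, 0), tp = c(0, 0, 33, 0),
                       fp = c(1, 0, 0, 0), fn = c(0, 0, 2, 0))
  conf <- matrix(0, 4, 4, dimnames = list(object_classes, object_classes))
  conf["flock", "flock"] <- 33
  conf["flock", "bird"] <- 1
  fx <- make_fixture_from_counts(counts, conf)
  tc2 <- tally_counts(match_detections(fx$detections, fx$annotations),
                      fx$detections, fx$annotations)
  fl <- tc2[tc2$class == "flock", ]
  expect_equal(c(fl$tp, fl$fn, fl$fp), c(33L, 2L, 0L))

  # one detection over no annotations: a lone false positive
  det1 <- detections(list(c(0, 0, 2, 2)), "bird", 0.5)
  ann0 <- annotations(list(), character(0))
  tc3 <- tally_counts(match_detections(det1, ann0), det1, ann0)
  expect_equal(tc3$fp[tc3$class == "bird"], 1L)
  expect_equal(sum(tc3$fp), 1L)
})

test_that("the four metrics reproduce hand-computed percentages", {
  flock <- list(tp = 33, fp = 0, fn = 2, tn = 0)
  expect_equal(precision(flock), 100.0)
  expect_equal(recall(flock), 94.3)
  expect_equal(f1_score(flock), 97.1)
  expect_equal(error_rate(flock), 5.7)

  heli <- list(tp = 4, fp = 0, fn = 0, tn = 0)
  expect_equal(precision(heli), 100.0)
  expect_equal(f1_score(heli), 100.0)
  expect_equal(error_rate(heli), 0.0)

  bird <- list(tp = 749, fp = 145, fn = 149, tn = 0)
  expect_equal(recall(bird), 83.4)
  expect_equal(error_rate(bird), 28.2)

  expect_equal(precision(list(tp = 1, fp = 1, fn = 0, tn = 0)), 50.0)
  expect_equal(recall(list(tp = 5, fp = 0, fn = 0, tn = 0)), 100.0)
  expect_equal(f1_score(list(tp = 0, fp = 1, fn = 1, tn = 0)), 0.0)
  # precision = recall = p implies F1 = p
  expect_equal(f1_score(list(tp = 3, fp = 1, fn = 1, tn = 0)), 75.0)
  expect_equal(error_rate(list(tp = 9, fp = 0, fn = 0, tn = 0)), 0.0)

  zero <- list(tp = 0, fp = 0, fn = 0, tn = 0)
  expect_error(precision(zero), "undefined")
  expect_error(recall(zero), "undefined")
  expect_error(f1_score(zero), "undefined")
  expect_error(error_rate(zero), "undefined")
})

test_that("F1 lies between precision and recall; metrics stay in [0, 100]", {
  set.seed(5)
  for (trial in 1:50) {
    c0 <- list(tp = sample(1:50, 1), fp = sample(0:30, 1),
               fn = sample(0:30, 1), tn = 0)
    p <- precision(c0); r <- recall(c0); f <- f1_score(c0); e <- error_rate(c0)
    for (v in c(p, r, f, e)) {
      expect_gte(v, 0); expect_lte(v, 100)
    }
    # rounding to one decimal can push F1 marginally past the tighter bound
    expect_lte(f, max(p, r) + 0.1)
    expect_gte(f, min(p, r) - 0.1)
  }
})

test_that("the confusion matrix separates cross-class and out-of-class FPs", {
  # perfect detector: diagonal equals the GT counts
  ann <- annotations(lapply(1:4, function(i) c(3 * i, 0, 3 * i + 2, 2)),
                     object_classes)
  det <- detections(lapply(1:4, function(i) c(3 * i, 0, 3 * i + 2, 2)),
                    object_classes, 0.9)
  cm <- confusion_matrix(match_detections(det, ann), det, ann)
  expect_equal(unname(diag(cm$counts)), rep(1L, 4))
  expect_equal(sum(cm$counts) - sum(diag(cm$counts)), 0L)

  # the published tallies: bug row (3, 48, 0, 0) and the bird FP split
  fx <- make_fixture_from_counts(published_counts(), published_confusion())
  m <- match_detections(fx$detections, fx$annotations)
  cm2 <- confusion_matrix(m, fx$detections, fx$annotations)
  expect_equal(unname(cm2$counts["bug", ]), c(3L, 48L, 0L, 0L))
  # 145 bird FPs = 4 cross-class (3 bug + 1 flock truth) + 141 out-of-class
  expect_equal(unname(cm2$counts["bug", "bird"] + cm2$counts["flock", "bird"]), 4L)
  expect_equal(unname(cm2$out_of_class_fp["bird"]), 141L)

  # row sums + out-of-class reconcile with per-class FP totals
  tc <- tally_counts(m, fx$detections, fx$annotations)
  for (cl in object_classes) {
    cross <- sum(cm2$counts[, cl]) - cm2$counts[cl, cl]
    expect_equal(cross + unname(cm2$out_of_class_fp[cl]),
                 tc$fp[tc$class == cl])
  }
})

test_that("tp + fn = gt for every class on random detection sets", {
  set.seed(9)
  for (trial in 1:20) {
    n_ann <- sample(0:10, 1); n_det <- sample(0:10, 1)
    ann <- annotations(lapply(seq_len(n_ann), function(i) {
      x <- 5 * i; c(x, 0, x + 3, 3)
    }), sample(object_classes, n_ann, replace = TRUE))
    det <- detections(lapply(seq_len(n_det), function(i) {
      x <- 5 * i + sample(0:4, 1); c(x, 0, x + 3, 3)
    }), sample(object_classes, n_det, replace = TRUE),
    runif(n_det))
    tc <- tally_counts(match_detections(det, ann), det, ann)
    expect_equal(tc$tp + tc$fn, tc$gt)
    expect_equal(sum(tc$fp), n_det - sum(tc$tp))
  }
})

test_that("the evaluation report round-trips through CSV", {
  fx <- make_fixture_from_counts(published_counts(), published_confusion())
  ev <- evaluate_detections(fx$detections, fx$annotations)
  stem <- tempfile("report")
  write_evaluation_report(ev, stem)
  metrics <- read.csv(paste0(stem, "_metrics.csv"))
  expect_equal(metrics$recall, c(83.4, 67.6, 94.3, 100.0))
  expect_equal(metrics$error_rate, c(28.2, 49.5, 5.7, 0.0))
  conf <- read.csv(paste0(stem, "_confusion.csv"))
  expect_equal(conf$bird[conf$truth == "bird"], 749)
  expect_equal(conf$bird[conf$truth == "out_of_class_fp"], 141)
})
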
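#' Run the full detection-to-trigger pipeline over a frame sequence
#'
#' Chains the whole system the way the deployed unit runs it: the
#' differential motion detector proposes candidate boxes per frame, the
#' classifier labels them (grouping birds into flocks), and the trigger
#' policy decides when the scaring actuator would fire. Optionally writes
#' the detection log, the trigger log, and every positive frame (any frame
#' with at least one surviving box) as PNG into `store_dir` — the local
#' stand-in for the unit's cloud upload.
#'
#' @param frames list of frame matrices (e.g. from [read_frames()] or
#'   [generate_scene()]).
#' @param detector a [motion_detector()].
#' @param classifier a classifier function, default
#'   [heuristic_classifier()].
#' @param policy a [trigger_policy()].
#' @param store_dir optional directory for logs and positive frames.
#' @return list with `boxes` (per-frame candidate boxes), `detections`
#'   (per-frame labeled detections), `events` (trigger events data.frame)
#'   and `store` (logical per frame).
#' @export
run_pipeline <- function(frames, detector = motion_detector(),
                         classifier = heuristic_classifier(),
                         policy = trigger_policy(), store_dir = NULL) {
  det_run <- detect_sequence(frames, detector)
  dets <- lapply(seq_along(frames), function(i) {
    classify_objects(frames[[i]], det_run$boxes[[i]], classifier)
  })
  events <- run_trigger(dets, policy)
  if (!is.null(store_dir)) {
    dir.create(store_dir, recursive = TRUE, showWarnings = FALSE)
    write_detection_log(det_run$boxes, file.path(store_dir, "detections.jsonl"))
    write_trigger_log(events, file.path(store_dir, "triggers.jsonl"))
    for (i in which(det_run$store)) {
      write_frame_png(frames[[i]],
                      file.path(store_dir, sprintf("frame_%05d.png", i - 1L)))
    }
  }
  list(boxes = det_run$boxes, detections = dets, events = events,
       store = det_run$store)
}
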
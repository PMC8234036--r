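#' Flock-only actuation policy
#'
#' The scaring actuator fires only for flocks: a flock detection whose
#' confidence is at least `confidence_threshold` (inclusive — "at least
#' 30%"), present in `confirm_frames` consecutive frames, and no earlier
#' than `cooldown_frames` frames after the previous event. Individual
#' birds never trigger, regardless of confidence. Defaults reproduce the
#' deployed behavior: threshold 0.30, single-frame confirmation, no
#' cooldown; multi-frame confirmation models evaluating a flock across the
#' several images in which it is captured, and the cooldown models
#' actuator duty limits.
#'
#' @param confidence_threshold minimum flock confidence in \[0, 1\],
#'   default 0.30.
#' @param confirm_frames consecutive qualifying frames required, >= 1.
#' @param cooldown_frames minimum frame gap after an event before the next
#'   may fire, >= 0.
#' @return an object of class `trigger_policy`.
#' @export
trigger_policy <- function(confidence_threshold = 0.30, confirm_frames = 1L,
                           cooldown_frames = 0L) {
  if (confidence_threshold < 0 || confidence_threshold > 1) {
    stop("confidence_threshold must lie in [0, 1]")
  }
  if (confirm_frames < 1) stop("confirm_frames must be >= 1")
  if (cooldown_frames < 0) stop("cooldown_frames must be >= 0")
  structure(list(confidence_threshold = confidence_threshold,
                 confirm_frames = as.integer(confirm_frames),
                 cooldown_frames = as.integer(cooldown_frames)),
            class = "trigger_policy")
}

#' Fresh trigger state
#'
#' @return list holding the consecutive-frame streak, the last event frame
#'   and the running frame index.
#' @export
trigger_state <- function() {
  list(streak = 0L, last_event = -Inf, frame = -1L)
}

#' Decide whether to trigger the actuator on one frame
#'
#' Feeds one frame's detections through the policy state machine. An event
#' records the frame index, the qualifying flock's box, and its
#' confidence; it abstracts the wireless signal that would switch the
#' scaring relay.
#'
#' @param dets detections data.frame for a single frame.
#' @param policy a [trigger_policy()].
#' @param state state from [trigger_state()] or a previous call.
#' @return list with `events` (data.frame `frame, x0, y0, x1, y1,
#'   confidence`, 0 or 1 rows) and the updated `state`.
#' @export
decide_trigger <- function(dets, policy = trigger_policy(),
                           state = trigger_state()) {
  stopifnot(inherits(policy, "trigger_policy"))
  state$frame <- state$frame + 1L
  qual <- dets[dets$label == "flock" &
                 dets$confidence >= policy$confidence_threshold, ,
               drop = FALSE]
  events <- data.frame(frame = integer(0), x0 = numeric(0), y0 = numeric(0),
                       x1 = numeric(0), y1 = numeric(0),
                       confidence = numeric(0))
  if (nrow(qual) > 0L) {
    state$streak <- state$streak + 1L
    off_cooldown <- state$frame - state$last_event > policy$cooldown_frames
    if (state$streak >= policy$confirm_frames && off_cooldown) {
      best <- qual[which.max(qual$confidence), ]
      events <- data.frame(frame = state$frame,
                           x0 = best$x0, y0 = best$y0,
                           x1 = best$x1, y1 = best$y1,
                           confidence = best$confidence)
      state$last_event <- state$frame
    }
  } else {
    state$streak <- 0L
  }
  list(events = events, state = state)
}

#' Run the trigger policy over a detection stream
#'
#' @param det_frames list of per-frame detections data.frames.
#' @param policy a [trigger_policy()].
#' @return data.frame of all trigger events.
#' @export
run_trigger <- function(det_frames, policy = trigger_policy()) {
  state <- trigger_state()
  out <- list()
  for (i in seq_along(det_frames)) {
    r <- decide_trigger(det_frames[[i]], policy, state)
    state <- r$state
    if (nrow(r$events)) out[[length(out) + 1L]] <- r$events
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(frame = integer(0), x0 = numeric(0), y0 = numeric(0),
               x1 = numeric(0), y1 = numeric(0), confidence = numeric(0))
}
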
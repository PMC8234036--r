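# shared internal helpers

# round half away from zero (the tables print 94.285... as 94.3, 49.47 as 49.5);
# base round() is banker's rounding, which would print 5.65 as 5.6
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Validate an axis-aligned bounding box
#'
#' Boxes everywhere in this package are 0-based, half-open pixel rectangles
#' `[x0, x1) x [y0, y1)`, stored as numeric vectors `c(x0, y0, x1, y1)`.
#'
#' @param box numeric length-4 vector `c(x0, y0, x1, y1)`.
#' @return the box, invisibly, after validation.
#' @keywords internal
check_box <- function(box) {
  if (!is.numeric(box) || length(box) != 4L) {
    stop("a bounding box must be a numeric vector c(x0, y0, x1, y1)")
  }
  if (box[3] <= box[1] || box[4] <= box[2]) {
    stop(sprintf("degenerate box [%s): x1 > x0 and y1 > y0 required",
                 paste(box, collapse = ", ")))
  }
  invisible(box)
}

box_area <- function(box) (box[3] - box[1]) * (box[4] - box[2])

box_center <- function(box) c((box[1] + box[3]) / 2, (box[2] + box[4]) / 2)

# empty boxes data.frame with the canonical columns
empty_boxes <- function() {
  data.frame(x0 = integer(0), y0 = integer(0),
             x1 = integer(0), y1 = integer(0))
}

empty_detections <- function() {
  cbind(empty_boxes(),
        data.frame(label = character(0), confidence = numeric(0)))
}

empty_annotations <- function() {
  cbind(empty_boxes(), data.frame(label = character(0)))
}

# rows of a box-bearing data.frame as a list of c(x0,y0,x1,y1) vectors
box_rows <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    as.numeric(c(df$x0[i], df$y0[i], df$x1[i], df$y1[i]))
  })
}
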
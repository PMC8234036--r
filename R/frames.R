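#' Grayscale frames
#'
#' A frame is a plain numeric matrix of 8-bit intensities in \[0, 255\],
#' indexed `[row, col]` with row = image y + 1 and col = image x + 1, so the
#' matrix has `height` rows and `width` columns. Color input is converted to
#' grayscale by the luma weights used for broadcast video before any
#' differencing takes place; the motion detector is intensity-based.
#'
#' @param pixels numeric matrix (grayscale, intensities in \[0, 255\]) or
#'   3-d RGB array on the same scale to coerce. PNG readers return
#'   \[0, 1\]; multiply by 255 first (as [read_frames()] does).
#' @return a numeric matrix with values in \[0, 255\].
#' @examples
#' f <- as_frame(matrix(0, 4, 4))
#' dim(f)
#' @export
as_frame <- function(pixels) {
  if (is.array(pixels) && length(dim(pixels)) == 3L) {
    d3 <- dim(pixels)[3]
    if (d3 >= 3L) {
      pixels <- 0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] +
        0.114 * pixels[, , 3]
    } else {
      pixels <- pixels[, , 1]
    }
  }
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("a frame must be a numeric matrix or an RGB array")
  }
  if (any(pixels < 0) || any(pixels > 255)) {
    stop("frame intensities must lie in [0, 255]")
  }
  pixels
}

check_same_dims <- function(a, b, what = "frames") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s have mismatched shapes: %dx%d vs %dx%d", what,
                 nrow(a), ncol(a), nrow(b), ncol(b)))
  }
}

#' Read and write portable graymap (PGM) images
#'
#' Minimal reader/writer for 8-bit PGM, supporting both the ASCII (`P2`) and
#' binary (`P5`) encodings on read; `write_pgm()` emits ASCII `P2` so that
#' fixtures stay plain text. Comments (`#`) in the header are honored.
#'
#' @param path file path.
#' @param frame numeric matrix of intensities in \[0, 255\].
#' @return `read_pgm()` returns a frame matrix; `write_pgm()` returns the
#'   path invisibly.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw_all <- readBin(con, "raw", n = file.info(path)$size)
  magic <- rawToChar(raw_all[1:2])
  if (!magic %in% c("P2", "P5")) stop("not a PGM file (P2/P5): ", path)
  # tokenize header: magic, width, height, maxval; skip comment lines
  toks <- character(0); i <- 3L; n <- length(raw_all)
  while (length(toks) < 3L && i <= n) {
    ch <- rawToChar(raw_all[i])
    if (ch == "#") {                      # comment to end of line
      while (i <= n && rawToChar(raw_all[i]) != "\n") i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      num <- ch
      while (i + 1L <= n && grepl("[0-9]", rawToChar(raw_all[i + 1L]))) {
        i <- i + 1L
        num <- paste0(num, rawToChar(raw_all[i]))
      }
      toks <- c(toks, num)
    }
    i <- i + 1L
  }
  w <- as.integer(toks[1]); h <- as.integer(toks[2])
  maxval <- as.integer(toks[3])
  if (magic == "P5") {
    # i rests on the single whitespace after maxval; pixel bytes follow it
    px <- as.integer(raw_all[i + seq_len(w * h)])
  } else {
    body <- rawToChar(raw_all[i:n])
    px <- as.integer(strsplit(trimws(body), "[[:space:]]+")[[1]])[seq_len(w * h)]
  }
  px <- px * (255 / maxval)
  matrix(px, nrow = h, ncol = w, byrow = TRUE)
}

#' @rdname read_pgm
#' @export
write_pgm <- function(frame, path) {
  frame <- as_frame(frame)
  vals <- as.integer(round(t(frame)))  # row-major scan order
  header <- sprintf("P2\n%d %d\n255", ncol(frame), nrow(frame))
  body <- paste(apply(matrix(vals, ncol = ncol(frame), byrow = TRUE), 1,
                      paste, collapse = " "), collapse = "\n")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ordered frame sequence from a directory
#'
#' Frames are the lexicographically sorted `.png` / `.pgm` files in `dir`;
#' all frames must share dimensions.
#'
#' @param dir directory of image files.
#' @param pattern filename filter, default PNG and PGM.
#' @return list of frame matrices.
#' @export
read_frames <- function(dir, pattern = "\\.(png|pgm)$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0L) stop("no frames matching ", pattern, " in ", dir)
  frames <- lapply(files, function(f) {
    if (grepl("\\.png$", f, ignore.case = TRUE)) {
      as_frame(png::readPNG(f) * 255)  # readPNG scales to [0, 1]
    } else {
      read_pgm(f)
    }
  })
  for (i in seq_along(frames)[-1]) {
    check_same_dims(frames[[1]], frames[[i]], "sequence frames")
  }
  frames
}

#' Write one frame as a PNG file
#'
#' @param frame intensity matrix in \[0, 255\].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_frame_png <- function(frame, path) {
  png::writePNG(as_frame(frame) / 255, path)
  invisible(path)
}
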
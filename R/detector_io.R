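# Detection file I/O and detector grid geometry.
#
# Detection files use an MOT-challenge-style comma-separated dialect:
#   frame,id,x,y,w,h,conf[,...]
# with 0-based frames, top-left + width/height box coordinates (converted
# to corner form at this boundary, fixing the corner-vs-center ambiguity
# once), and confidence in [0, 1]. The id field is ignored on input and
# written as -1 for anonymous detections; the simulator writes real plant
# ids in its ground-truth files.

#' Read an MOT-style detection file
#'
#' @param path Path to a text file, one detection per line:
#'   `frame,id,x,y,w,h,conf` (extra trailing fields ignored). Blank lines
#'   are skipped.
#' @param conf_threshold Detections with confidence strictly below this are
#'   dropped at read time. Default 0 (keep all).
#' @return A `detections` data frame with columns `frame`, `id`, `x1`,
#'   `y1`, `x2`, `y2`, `conf`, sorted by frame; zero rows for an empty
#'   file.
#' @export
read_detections <- function(path, conf_threshold = 0) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L)
    return(data.frame(frame = integer(0), id = integer(0),
                      x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0),
                      conf = numeric(0)))
  parts <- strsplit(lines, ",", fixed = TRUE)
  rows <- vector("list", length(parts))
  for (k in seq_along(parts)) {
    p <- trimws(parts[[k]])
    if (length(p) < 7L)
      stop(sprintf("line %d: expected at least 7 comma-separated fields",
                   lineno[k]), call. = FALSE)
    v <- suppressWarnings(as.numeric(p[1:7]))
    if (anyNA(v))
      stop(sprintf("line %d: non-numeric field", lineno[k]), call. = FALSE)
    if (v[1L] < 0 || v[1L] != floor(v[1L]))
      stop(sprintf("line %d: frame index must be a nonnegative integer",
                   lineno[k]), call. = FALSE)
    if (v[5L] <= 0 || v[6L] <= 0)
      stop(sprintf("line %d: width and height must be positive", lineno[k]),
           call. = FALSE)
    rows[[k]] <- v
  }
  m <- do.call(rbind, rows)
  df <- data.frame(frame = as.integer(m[, 1L]), id = as.integer(m[, 2L]),
                   x1 = m[, 3L], y1 = m[, 4L],
                   x2 = m[, 3L] + m[, 5L], y2 = m[, 4L] + m[, 6L],
                   conf = m[, 7L])
  df <- df[df$conf >= conf_threshold, , drop = FALSE]
  df <- df[order(df$frame), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("detections", "data.frame")
  df
}

#' Write detections in the MOT-style dialect
#'
#' Inverse of [read_detections()]; the round trip is lossless for valid
#' records.
#'
#' @param df Data frame with columns `frame`, `x1`, `y1`, `x2`, `y2`,
#'   `conf`, and optionally `id` (written as -1 when absent).
#' @param path Output path.
#' @export
write_detections <- function(df, path) {
  id <- if ("id" %in% names(df)) df$id else rep(-1L, nrow(df))
  conf <- if ("conf" %in% names(df)) df$conf else rep(1, nrow(df))
  lines <- sprintf("%d,%d,%s,%s,%s,%s,%s",
                   as.integer(df$frame), as.integer(id),
                   format(df$x1, digits = 15, trim = TRUE, scientific = FALSE),
                   format(df$y1, digits = 15, trim = TRUE, scientific = FALSE),
                   format(df$x2 - df$x1, digits = 15, trim = TRUE, scientific = FALSE),
                   format(df$y2 - df$y1, digits = 15, trim = TRUE, scientific = FALSE),
                   format(conf, digits = 15, trim = TRUE, scientific = FALSE))
  writeLines(lines, path)
  invisible(path)
}

#' Detector output-grid specification
#'
#' Describes the single-stage detection head geometry of a YOLO-family
#' detector: a square input, one output grid per stride, `B` boxes per
#' grid cell and `C` classes. Each cell predicts `B * (5 + C)` numbers --
#' per box the four box attributes, one objectness score, and `C` class
#' scores.
#'
#' @param input_size Square input resolution (px), divisible by every
#'   stride.
#' @param strides Integer downsampling factors, one per prediction scale.
#' @param boxes_per_cell Boxes predicted per grid cell (`B >= 1`).
#' @param n_classes Number of classes (`C >= 1`).
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(input_size, strides = c(32L, 16L, 8L),
                      boxes_per_cell = 3L, n_classes = 1L) {
  input_size <- as.integer(input_size)
  strides <- as.integer(strides)
  if (boxes_per_cell < 1L) stop("boxes_per_cell must be >= 1", call. = FALSE)
  if (n_classes < 1L) stop("n_classes must be >= 1", call. = FALSE)
  if (length(strides) < 1L || any(strides < 1L))
    stop("strides must be positive integers", call. = FALSE)
  if (any(input_size %% strides != 0L))
    stop("input_size must be divisible by every stride", call. = FALSE)
  structure(list(input_size = input_size, strides = strides,
                 boxes_per_cell = as.integer(boxes_per_cell),
                 n_classes = as.integer(n_classes)),
            class = "grid_spec")
}

#' Detection-kernel depth
#'
#' The 1x1 detection kernel has depth `B * (5 + C)`; for one class and
#' three boxes per cell that is 18.
#'
#' @param spec A [grid_spec()].
#' @return Integer kernel depth.
#' @export
kernel_depth <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  spec$boxes_per_cell * (5L + spec$n_classes)
}

#' Prediction-grid side lengths
#'
#' One square grid per stride: `input_size / stride`, in stride order.
#' A 416-px input with strides 32/16/8 predicts on 13, 26 and 52 cell
#' grids; the two-scale tiny variant keeps 13 and 26.
#'
#' @param spec A [grid_spec()].
#' @return Integer vector of grid side lengths.
#' @export
grid_sizes <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  as.integer(spec$input_size / spec$strides)
}
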
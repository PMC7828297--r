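# Finish-line counting. Counting by raw track ids over-counts badly
# whenever the detector blinks (a re-detected plant gets a fresh id), so a
# plant is counted only when the trace between its consecutive track
# centers crosses a fixed finish line, and each track id counts at most
# once. Short-lived spurious tracks usually expire before reaching the
# line and so never count.

#' Construct a finish line
#'
#' @param x1,y1,x2,y2 Endpoints C and D of the line segment, image
#'   coordinates (px).
#' @return A `finish_line` (a [segment()]).
#' @export
finish_line <- function(x1, y1, x2, y2) {
  structure(segment(c(x1, y1), c(x2, y2)), class = c("finish_line", "matrix"))
}

#' Default finish line for a frame
#'
#' Horizontal line spanning the full frame width at 90% of the frame
#' height -- near the bottom edge where tracks are mature, but with margin
#' so a coasting track can still reach it.
#'
#' @param frame_width,frame_height Frame dimensions (px).
#' @export
default_finish_line <- function(frame_width, frame_height) {
  finish_line(0, 0.9 * frame_height, frame_width, 0.9 * frame_height)
}

#' Test a track against the finish line
#'
#' Emits a count event iff the segment joining the track's previous and
#' current centers intersects the line, the track has a previous center
#' (it has lived at least two frames), and it has not been counted before.
#' Crossing direction is ignored; with the once-per-track rule this cannot
#' double count a jittering track.
#'
#' @param track A `track`.
#' @param line A [finish_line()].
#' @return `NULL`, or a list `(track_id, point)` where `point` is the
#'   current center at the crossing frame.
#' @export
check_crossing <- function(track, line) {
  if (isTRUE(track$counted) || is.null(track$prev_center)) return(NULL)
  if (all(track$prev_center == track$curr_center)) return(NULL)
  trace <- segment(track$prev_center, track$curr_center)
  if (segments_intersect(trace, line))
    list(track_id = track$id, point = track$curr_center)
  else NULL
}

as_detection_stream <- function(detection_stream) {
  if (is.data.frame(detection_stream)) {
    df <- detection_stream
    stopifnot(all(c("frame", "x1", "y1", "x2", "y2") %in% names(df)))
    if (nrow(df) && any(df$frame < 0))
      stop("malformed detection stream: negative frame index", call. = FALSE)
    n_frames <- if (nrow(df)) max(df$frame) + 1L else 0L
    out <- rep(list(boxes()), n_frames)
    for (f in unique(df$frame)) {
      sub <- df[df$frame == f, c("x1", "y1", "x2", "y2"), drop = FALSE]
      out[[f + 1L]] <- as.matrix(sub)
    }
    return(out)
  }
  if (is.list(detection_stream)) {
    return(lapply(detection_stream, as_box_matrix))
  }
  stop("detection stream must be a data frame or a per-frame list of boxes",
       call. = FALSE)
}

#' Run the full counting pipeline
#'
#' For each frame (0-indexed; frames absent from the stream are processed
#' with zero detections, i.e. predict-only): step the tracker, then test
#' every live track against the finish line. Deterministic given inputs
#' and configuration.
#'
#' @param detection_stream Either a `detections` data frame (columns
#'   `frame`, `x1`, `y1`, `x2`, `y2`, see [read_detections()]) or a list of
#'   per-frame box matrices, element `i` holding frame `i - 1`.
#' @param line A [finish_line()].
#' @param config A [stand_config()].
#' @param n_frames Process at least this many frames (padding the stream
#'   with empty frames so coasting tracks can finish crossing); default is
#'   the stream's own length.
#' @param verbose Print per-frame track statistics.
#' @return A `count_result`: list with `count`, `events` (data frame
#'   `frame`, `track_id`, `x`, `y`), `frames_processed`, `tracks_created`,
#'   `tracks_deleted`, `tracks_live`.
#' @examples
#' dets <- lapply(0:9, function(f) boxes(box(95, 10 * f, 125, 40 + 10 * f)))
#' run_pipeline(dets, finish_line(0, 75, 200, 75))
#' @export
run_pipeline <- function(detection_stream, line, config = stand_config(),
                         n_frames = NULL, verbose = FALSE) {
  frames <- as_detection_stream(detection_stream)
  if (!is.null(n_frames) && n_frames > length(frames))
    frames <- c(frames, rep(list(boxes()), n_frames - length(frames)))
  tracker <- tracker_create(config)
  events <- list()
  for (f in seq_along(frames)) {
    st <- step_tracks(tracker, frames[[f]])
    tracker <- st$tracker
    for (i in seq_along(tracker$tracks)) {
      ev <- check_crossing(tracker$tracks[[i]], line)
      if (!is.null(ev)) {
        tracker$tracks[[i]]$counted <- TRUE
        events[[length(events) + 1L]] <-
          data.frame(frame = f - 1L, track_id = ev$track_id,
                     x = ev$point[[1L]], y = ev$point[[2L]])
      }
    }
    if (verbose)
      message(sprintf(
        "frame %d: %d detections, %d live tracks, count %d",
        f - 1L, nrow(frames[[f]]), length(tracker$tracks), length(events)))
  }
  events <- if (length(events)) do.call(rbind, events)
  else data.frame(frame = integer(0), track_id = integer(0),
                  x = numeric(0), y = numeric(0))
  structure(list(
    count = nrow(events),
    events = events,
    frames_processed = length(frames),
    tracks_created = tracker$n_created,
    tracks_deleted = tracker$n_deleted,
    tracks_live = length(tracker$tracks)
  ), class = "count_result")
}

#' @export
print.count_result <- function(x, ...) {
  cat(sprintf(
    "<count_result> count %d over %d frames (%d tracks created, %d deleted, %d live)\n",
    x$count, x$frames_processed, x$tracks_created, x$tracks_deleted,
    x$tracks_live))
  if (nrow(x$events)) {
    cat("events (frame, track_id):\n")
    print(x$events, row.names = FALSE)
  }
  invisible(x)
}
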
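# Track lifecycle: spawn on unmatched detection, Kalman predict/update,
# coast while unmatched, delete after max_age consecutive unmatched frames.
#
# A tracker is an ordinary list so stepping is purely functional: every
# step returns a new tracker state plus the association that produced it.

#' Initialize a track from a detection
#'
#' The measured components come from the detection box; all four rates
#' start at zero with large prior variance, so the first updates establish
#' the velocity. New tracks are immediately eligible for counting -- there
#' is no probation period.
#'
#' @param det Detection box.
#' @param next_id Positive integer id, never reused within a run.
#' @param config A [stand_config()].
#' @return A `track`: list with `id`, `state`, `cov`, `time_since_update`,
#'   `hits`, `counted`, `prev_center`, `curr_center`.
#' @export
init_track <- function(det, next_id, config = stand_config()) {
  z <- box_to_measurement(det)
  structure(list(
    id = as.integer(next_id),
    state = c(unname(z), rep(0, 4)),
    cov = config_P0(config),
    time_since_update = 0L,
    hits = 1L,
    counted = FALSE,
    prev_center = NULL,
    curr_center = unname(z[1:2])
  ), class = "track")
}

#' Create an empty tracker
#'
#' @param config A [stand_config()].
#' @return List of class `tracker` holding live tracks, the id counter and
#'   creation/deletion statistics.
#' @export
tracker_create <- function(config = stand_config()) {
  structure(list(
    tracks = list(),
    next_id = 1L,
    frame = -1L,
    n_created = 0L,
    n_deleted = 0L,
    config = config
  ), class = "tracker")
}

#' Advance the tracker by one frame of detections
#'
#' One epoch of the counting loop: predict every live track forward,
#' associate predictions with this frame's detections by maximum total IoU
#' under the IoU gate, update matched tracks with their measurement,
#' increment the unmatched-age of coasting tracks, spawn a new track per
#' unmatched detection, and delete tracks unmatched for more than
#' `max_age` frames. Centers are recorded before and after so the counter
#' can test the trace segment between consecutive frames.
#'
#' @param tracker A `tracker` (see [tracker_create()]).
#' @param detections `m x 4` box matrix (possibly zero rows).
#' @return List with `tracker` (advanced state) and `association` (the
#'   [associate()] result; match rows refer to this frame's live-track
#'   order and detection order). The association's `track_ids` element
#'   gives the track id for each pre-deletion live track row.
#' @export
step_tracks <- function(tracker, detections) {
  config <- tracker$config
  det <- as_box_matrix(detections)
  Q <- config_Q(config)
  R <- config_R(config)

  # predict all live tracks; roll centers so prev/curr span this frame
  tracks <- lapply(tracker$tracks, function(tr) {
    pr <- kf_predict(tr$state, tr$cov, Q)
    tr$state <- pr$state
    tr$cov <- pr$cov
    tr$prev_center <- tr$curr_center
    tr$curr_center <- pr$state[1:2]
    tr
  })

  pred_boxes <- if (length(tracks))
    do.call(rbind, lapply(tracks, function(tr) state_to_box(tr$state)))
  else boxes()
  assoc <- associate(det, pred_boxes, config$iou_threshold)
  assoc$track_ids <- vapply(tracks, function(tr) tr$id, integer(1))

  if (nrow(assoc$matches)) {
    for (k in seq_len(nrow(assoc$matches))) {
      i <- assoc$matches[k, "track"]
      j <- assoc$matches[k, "detection"]
      z <- box_to_measurement(det[j, ])
      up <- kf_update(tracks[[i]]$state, tracks[[i]]$cov, unname(z), R)
      tracks[[i]]$state <- up$state
      tracks[[i]]$cov <- up$cov
      tracks[[i]]$time_since_update <- 0L
      tracks[[i]]$hits <- tracks[[i]]$hits + 1L
      tracks[[i]]$curr_center <- up$state[1:2]
    }
  }
  for (i in assoc$unmatched_tracks)
    tracks[[i]]$time_since_update <- tracks[[i]]$time_since_update + 1L

  n_created <- 0L
  next_id <- tracker$next_id
  for (j in assoc$unmatched_detections) {
    tracks[[length(tracks) + 1L]] <- init_track(det[j, ], next_id, config)
    next_id <- next_id + 1L
    n_created <- n_created + 1L
  }

  keep <- vapply(tracks, function(tr)
    tr$time_since_update <= config$max_age, logical(1))
  n_deleted <- sum(!keep)
  tracks <- tracks[keep]

  tracker$tracks <- tracks
  tracker$next_id <- next_id
  tracker$frame <- tracker$frame + 1L
  tracker$n_created <- tracker$n_created + n_created
  tracker$n_deleted <- tracker$n_deleted + n_deleted
  list(tracker = tracker, association = assoc)
}

#' @export
print.tracker <- function(x, ...) {
  cat(sprintf("<tracker> frame %d: %d live, %d created, %d deleted\n",
              x$frame, length(x$tracks), x$n_created, x$n_deleted))
  invisible(x)
}
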
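# Optimal one-to-one assignment of detections to predicted tracks.
#
# The affinity is IoU (assignment cost 1 - IoU), solved exactly by the
# Hungarian algorithm with potentials; instances here are small (tens of
# boxes) so the O(n^3) solver in plain R is ample. After the optimal
# assignment, pairs below the IoU gate are demoted to unmatched on both
# sides -- the gate double-checks the association, it does not steer it.

# Hungarian algorithm for a square cost matrix (minimization).
# Returns for each row the assigned column. Deterministic.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost))
  if (n == 0L) return(integer(0))
  # potentials and matching, 0-based virtual column 0 stored at index 1
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)   # p[j+1] = row matched to column j (0 = free)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free_j <- which(!used[-1L])          # candidate columns, 1-based
      cur <- cost[i0, free_j] - u[i0 + 1L] - v[free_j + 1L]
      upd <- cur < minv[free_j + 1L]
      if (any(upd)) {
        minv[free_j[upd] + 1L] <- cur[upd]
        way[free_j[upd] + 1L] <- j0
      }
      k <- which.min(minv[free_j + 1L])
      delta <- minv[free_j[k] + 1L]
      j1 <- free_j[k]
      uu <- which(used)                    # includes virtual column 0
      u[p[uu] + 1L] <- u[p[uu] + 1L] + delta
      v[uu] <- v[uu] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign_row <- integer(n)
  for (j in seq_len(n)) assign_row[p[j + 1L]] <- j
  assign_row
}

#' Associate detections with predicted tracks
#'
#' Solves the maximum-total-IoU one-to-one assignment between predicted
#' track boxes and detections, then rejects any assigned pair whose IoU is
#' below `iou_threshold`; rejected pairs are reported as unmatched on both
#' sides. The three output sets partition the inputs. Ties between
#' equal-affinity assignments are broken toward low (track position,
#' detection index) pairs by an infinitesimal cost perturbation, so the
#' result is deterministic.
#'
#' @param detections `m x 4` box matrix of detections.
#' @param predicted_tracks `n x 4` box matrix of predicted track boxes
#'   (one row per live track, in track order).
#' @param iou_threshold Gate in `[0, 1]`.
#' @return List of class `association` with `matches` (2-column matrix
#'   `track`, `detection` of row indices into the inputs),
#'   `unmatched_detections` and `unmatched_tracks` (integer index vectors),
#'   and `iou` (the full IoU matrix).
#' @export
associate <- function(detections, predicted_tracks, iou_threshold = 0.3) {
  stopifnot(iou_threshold >= 0, iou_threshold <= 1)
  det <- as_box_matrix(detections)
  trk <- as_box_matrix(predicted_tracks)
  n <- nrow(trk); m <- nrow(det)
  empty <- matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("track", "detection")))
  if (n == 0L || m == 0L) {
    return(structure(list(matches = empty,
                          unmatched_detections = seq_len(m),
                          unmatched_tracks = seq_len(n),
                          iou = iou_matrix(trk, det)),
                     class = "association"))
  }
  iomat <- iou_matrix(trk, det)
  d <- max(n, m)
  # pad to square with a cost worse than any real pair; the tiny index
  # perturbation breaks exact ties deterministically without disturbing
  # meaningful IoU differences
  cost <- matrix(2, d, d)
  tie <- outer(seq_len(n) - 1L, seq_len(m) - 1L,
               function(i, j) (i * m + j) * 1e-12)
  cost[seq_len(n), seq_len(m)] <- (1 - iomat) + tie
  assign_col <- solve_assignment(cost)
  matches <- empty
  for (i in seq_len(n)) {
    j <- assign_col[i]
    if (j <= m && iomat[i, j] >= iou_threshold && iomat[i, j] > 0)
      matches <- rbind(matches, cbind(track = i, detection = j))
  }
  structure(list(
    matches = matches,
    unmatched_detections = setdiff(seq_len(m), matches[, "detection"]),
    unmatched_tracks = setdiff(seq_len(n), matches[, "track"]),
    iou = iomat
  ), class = "association")
}
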
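# Axis-aligned boxes, the center/area/aspect measurement space, and
# segment-intersection tests used by the finish-line counter.
#
# Coordinate convention: pixel coordinates with the origin at the top-left
# corner, x increasing rightward and y increasing downward. Coordinates are
# continuous (sub-pixel positions are allowed); a box is the closed real
# rectangle [x1, x2] x [y1, y2].

#' Construct an axis-aligned bounding box
#'
#' A box is a length-4 numeric vector `c(x1, y1, x2, y2)` of corner
#' coordinates with `x2 > x1` and `y2 > y1`. Collections of boxes are
#' 4-column matrices with one row per box (see [boxes()]).
#'
#' @param x1,y1 Top-left corner (px).
#' @param x2,y2 Bottom-right corner (px).
#' @return Named numeric vector with elements `x1`, `y1`, `x2`, `y2`.
#' @examples
#' box(90, 30, 110, 70)
#' @export
box <- function(x1, y1, x2, y2) {
  b <- c(x1 = as.numeric(x1), y1 = as.numeric(y1),
         x2 = as.numeric(x2), y2 = as.numeric(y2))
  validate_box(b)
  b
}

validate_box <- function(b) {
  if (length(b) != 4L || !all(is.finite(b)))
    stop("box must be 4 finite coordinates (x1, y1, x2, y2)", call. = FALSE)
  if (b[[3L]] <= b[[1L]] || b[[4L]] <= b[[2L]])
    stop("box must have strictly positive width and height", call. = FALSE)
  invisible(b)
}

#' Assemble a box matrix
#'
#' @param ... Boxes created by [box()], or nothing for an empty set.
#' @return Numeric matrix with columns `x1`, `y1`, `x2`, `y2`; zero rows
#'   when called with no arguments.
#' @export
boxes <- function(...) {
  bs <- list(...)
  if (length(bs) == 0L)
    return(matrix(numeric(0), ncol = 4L,
                  dimnames = list(NULL, c("x1", "y1", "x2", "y2"))))
  m <- do.call(rbind, bs)
  colnames(m) <- c("x1", "y1", "x2", "y2")
  m
}

as_box_matrix <- function(b) {
  if (is.matrix(b)) {
    stopifnot(ncol(b) == 4L)
    return(b)
  }
  if (is.numeric(b) && length(b) == 4L) return(boxes(b))
  stop("expected a box or a 4-column box matrix", call. = FALSE)
}

#' Intersection-over-union of two boxes
#'
#' Area of the intersection divided by the area of the union. Boxes that
#' only share an edge have a zero-area intersection and therefore IoU 0.
#'
#' @param a,b Boxes (see [box()]).
#' @return IoU in `[0, 1]`; 0 for disjoint boxes, 1 iff `a == b`.
#' @examples
#' iou(box(0, 0, 10, 10), box(5, 0, 15, 10)) # 1/3
#' @export
iou <- function(a, b) {
  validate_box(a); validate_box(b)
  iou_matrix(boxes(a), boxes(b))[1L, 1L]
}

#' Pairwise IoU matrix
#'
#' @param a `n x 4` box matrix; @param b `m x 4` box matrix.
#' @return `n x m` matrix of IoU values.
#' @export
iou_matrix <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  n <- nrow(a); m <- nrow(b)
  if (n == 0L || m == 0L) return(matrix(numeric(0), nrow = n, ncol = m))
  ix1 <- outer(a[, 1L], b[, 1L], pmax)
  iy1 <- outer(a[, 2L], b[, 2L], pmax)
  ix2 <- outer(a[, 3L], b[, 3L], pmin)
  iy2 <- outer(a[, 4L], b[, 4L], pmin)
  iw <- pmax(ix2 - ix1, 0)
  ih <- pmax(iy2 - iy1, 0)
  inter <- iw * ih
  area_a <- (a[, 3L] - a[, 1L]) * (a[, 4L] - a[, 2L])
  area_b <- (b[, 3L] - b[, 1L]) * (b[, 4L] - b[, 2L])
  out <- inter / (outer(area_a, area_b, `+`) - inter)
  dimnames(out) <- NULL
  out
}

#' Convert a box to measurement space
#'
#' The tracker observes each box as `z = (u, v, s, r)`: the horizontal and
#' vertical pixel location of the box center, the box area in px^2, and the
#' width/height aspect ratio. Area and aspect ratio -- rather than width and
#' height -- are the filtered quantities, so leaf-flutter that changes box
#' shape at roughly constant size moves only `r`.
#'
#' @param b A box.
#' @return Named numeric vector `c(u, v, s, r)`.
#' @examples
#' box_to_measurement(box(90, 30, 110, 70)) # u=100 v=50 s=800 r=0.5
#' @export
box_to_measurement <- function(b) {
  validate_box(b)
  w <- b[[3L]] - b[[1L]]
  h <- b[[4L]] - b[[2L]]
  c(u = (b[[1L]] + b[[3L]]) / 2, v = (b[[2L]] + b[[4L]]) / 2,
    s = w * h, r = w / h)
}

#' Convert a measurement back to a box
#'
#' Inverse of [box_to_measurement()]: `w = sqrt(s * r)`, `h = sqrt(s / r)`,
#' centered at `(u, v)`.
#'
#' @param m Numeric vector `c(u, v, s, r)` with `s > 0`, `r > 0`.
#' @return A box.
#' @export
measurement_to_box <- function(m) {
  if (length(m) != 4L || !all(is.finite(m)))
    stop("measurement must be 4 finite values (u, v, s, r)", call. = FALSE)
  if (m[[3L]] <= 0 || m[[4L]] <= 0)
    stop("measurement requires s > 0 and r > 0", call. = FALSE)
  w <- sqrt(m[[3L]] * m[[4L]])
  h <- sqrt(m[[3L]] / m[[4L]])
  box(m[[1L]] - w / 2, m[[2L]] - h / 2, m[[1L]] + w / 2, m[[2L]] + h / 2)
}

#' Construct a 2-D segment
#'
#' @param p1,p2 Numeric length-2 points (px); must differ.
#' @return A 2x2 matrix with rows `p1`, `p2`.
#' @export
segment <- function(p1, p2) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  if (length(p1) != 2L || length(p2) != 2L || !all(is.finite(c(p1, p2))))
    stop("segment endpoints must be finite 2-D points", call. = FALSE)
  if (all(p1 == p2))
    stop("segment endpoints must differ", call. = FALSE)
  rbind(p1 = p1, p2 = p2)
}

# Orientation of the ordered triple (p, q, r): >0 counter-clockwise in a
# y-up frame (sign is irrelevant here, only agreement/zero matters).
orient <- function(p, q, r) {
  (q[1L] - p[1L]) * (r[2L] - p[2L]) - (q[2L] - p[2L]) * (r[1L] - p[1L])
}

on_segment <- function(p, q, r) {
  # collinear r assumed; is r within the bounding box of pq?
  min(p[1L], q[1L]) <= r[1L] && r[1L] <= max(p[1L], q[1L]) &&
    min(p[2L], q[2L]) <= r[2L] && r[2L] <= max(p[2L], q[2L])
}

#' Do two closed segments intersect?
#'
#' Standard orientation test with collinear/on-segment handling. Endpoints
#' count: a trace endpoint lying exactly on the finish line is an
#' intersection, so a plant whose center lands on the line is counted.
#'
#' @param a,b Segments (see [segment()]).
#' @return `TRUE` iff the closed segments share at least one point.
#' @export
segments_intersect <- function(a, b) {
  p1 <- a[1L, ]; p2 <- a[2L, ]; q1 <- b[1L, ]; q2 <- b[2L, ]
  d1 <- orient(q1, q2, p1)
  d2 <- orient(q1, q2, p2)
  d3 <- orient(p1, p2, q1)
  d4 <- orient(p1, p2, q2)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
    return(TRUE)
  if (d1 == 0 && on_segment(q1, q2, p1)) return(TRUE)
  if (d2 == 0 && on_segment(q1, q2, p2)) return(TRUE)
  if (d3 == 0 && on_segment(p1, p2, q1)) return(TRUE)
  if (d4 == 0 && on_segment(p1, p2, q2)) return(TRUE)
  FALSE
}
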
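# Independent oracles and fixture generators shared across tests.

# Random valid box within a bound.
random_box <- function(lim = 100) {
  x1 <- runif(1, 0, lim - 2); y1 <- runif(1, 0, lim - 2)
  box(x1, y1, x1 + runif(1, 1, lim / 2), y1 + runif(1, 1, lim / 2))
}

random_box_matrix <- function(n, lim = 100) {
  do.call(boxes, lapply(seq_len(n), function(i) random_box(lim)))
}

# Brute-force maximum total IoU over all complete injective assignments
# of the smaller side into the larger (IoU >= 0, so leaving a pair
# unassigned never increases the total).
brute_force_total_iou <- function(iomat) {
  n <- nrow(iomat); m <- ncol(iomat)
  if (n == 0L || m == 0L) return(0)
  if (n > m) return(brute_force_total_iou(t(iomat)))
  best <- -Inf
  rec <- function(i, used, tot) {
    if (i > n) {
      if (tot > best) best <<- tot
      return(invisible())
    }
    for (j in seq_len(m)) {
      if (!used[j]) {
        used[j] <- TRUE
        rec(i + 1L, used, tot + iomat[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, m), 0)
  best
}

# Closed-form parametric segment intersection (solves p + t*r = q + u*s),
# an independent route from the orientation tests in the package.
seg_intersect_oracle <- function(a, b) {
  p <- a[1L, ]; r <- a[2L, ] - a[1L, ]
  q <- b[1L, ]; s <- b[2L, ] - b[1L, ]
  rxs <- r[1L] * s[2L] - r[2L] * s[1L]
  qp <- q - p
  qpxr <- qp[1L] * r[2L] - qp[2L] * r[1L]
  if (rxs == 0) {
    if (qpxr != 0) return(FALSE)
    t0 <- sum(qp * r) / sum(r * r)
    t1 <- t0 + sum(s * r) / sum(r * r)
    return(max(min(t0, t1), 0) <= min(max(t0, t1), 1))
  }
  t <- (qp[1L] * s[2L] - qp[2L] * s[1L]) / rxs
  u <- qpxr / rxs
  t >= 0 && t <= 1 && u >= 0 && u <= 1
}

# Build a perfect (noise-free) constant-velocity detection stream for one
# object: returns a list of 1-row box matrices.
constant_velocity_stream <- function(n_frames, start_center, vel, w, h) {
  lapply(seq_len(n_frames) - 1L, function(f) {
    cx <- start_center[1L] + vel[1L] * f
    cy <- start_center[2L] + vel[2L] * f
    boxes(box(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2))
  })
}

expect_psd_symmetric <- function(P, tol = 1e-9) {
  expect_lt(max(abs(P - t(P))), tol)
  expect_gt(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values), -tol)
}
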
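cfg <- stand_config()

test_that("kf_predict applies constant-velocity propagation", {
  Q <- diag(8) * 0.1
  P <- diag(8)
  pr <- kf_predict(c(0, 0, 100, 1, 5, 10, 0, 0), P, Q)
  expect_equal(pr$state, c(5, 10, 100, 1, 5, 10, 0, 0))
  # zero rates: state unchanged
  pr0 <- kf_predict(c(3, 4, 50, 2, 0, 0, 0, 0), P, Q)
  expect_equal(pr0$state, c(3, 4, 50, 2, 0, 0, 0, 0))
  # two successive predicts: closed-form linear propagation
  st <- c(0, 0, 100, 1, 5, 10, 2, 0.01)
  pr2 <- kf_predict(kf_predict(st, P, Q)$state, P, Q)
  expect_equal(pr2$state[1:4], c(10, 20, 104, 1.02))
  expect_equal(pr2$state[5:8], st[5:8])
})

test_that("kf_update limits behave as a Kalman filter must", {
  P <- diag(8)
  st <- c(10, 10, 100, 1, 1, 1, 0, 0)
  z <- c(14, 8, 120, 1.2)
  # zero measurement noise: posterior measured components equal z exactly
  up <- kf_update(st, P, z, matrix(0, 4, 4))
  expect_equal(up$state[1:4], z, tolerance = 1e-12)
  # (near-)certain prior: posterior stays at the prior
  up2 <- kf_update(st, diag(8) * 1e-12, z, diag(4))
  expect_equal(up2$state, st, tolerance = 1e-6)
  # scalar analogue: prior var 1, meas var 1 -> gain 0.5 on u
  up3 <- kf_update(st, diag(8), c(20, 10, 100, 1), diag(4))
  expect_equal(up3$state[1], (10 + 20) / 2)
  # posterior no larger than prior (trace)
  expect_lte(sum(diag(up3$cov)), sum(diag(diag(8))))
})

test_that("covariance stays symmetric PSD over random filter sequences", {
  set.seed(99)
  Q <- diag(c(rep(1, 4), rep(0.01, 4)))
  R <- diag(c(1, 1, 10, 0.01))
  for (rep in 1:20) {
    st <- c(runif(2, 0, 100), runif(1, 50, 500), runif(1, 0.5, 2), rnorm(4))
    P <- crossprod(matrix(rnorm(64), 8, 8)) + diag(8)
    for (k in 1:25) {
      pr <- kf_predict(st, P, Q)
      expect_psd_symmetric(pr$cov)
      z <- pr$state[1:4] + c(rnorm(2), rnorm(1, 0, 3), rnorm(1, 0, 0.05))
      z[3] <- max(z[3], 1); z[4] <- max(z[4], 0.1)
      up <- kf_update(pr$state, pr$cov, z, R)
      expect_psd_symmetric(up$cov)
      st <- up$state; P <- up$cov
    }
  }
})

test_that("init_track converts the box and starts at rest", {
  tr <- init_track(box(90, 30, 110, 70), 1L, cfg)
  expect_equal(tr$state, c(100, 50, 800, 0.5, 0, 0, 0, 0))
  expect_identical(tr$id, 1L)
  expect_false(tr$counted)
  expect_identical(tr$time_since_update, 0L)
  tr2 <- init_track(box(0, 0, 5, 5), 2L, cfg)
  expect_false(tr$id == tr2$id)
  # zero process noise, zero initial rates: predict leaves the center put
  pr <- kf_predict(tr$state, tr$cov, matrix(0, 8, 8))
  expect_equal(pr$state[1:2], c(100, 50))
})

test_that("associate gates and partitions", {
  trk <- boxes(box(0, 0, 10, 10))
  det_hi <- boxes(box(1, 0, 11, 10))   # iou 9/11
  det_lo <- boxes(box(8, 8, 30, 30))   # iou well below 0.3
  a <- associate(det_hi, trk, 0.3)
  expect_equal(nrow(a$matches), 1L)
  expect_length(a$unmatched_detections, 0)
  expect_length(a$unmatched_tracks, 0)
  b <- associate(det_lo, trk, 0.3)
  expect_equal(nrow(b$matches), 0L)
  expect_identical(b$unmatched_detections, 1L)
  expect_identical(b$unmatched_tracks, 1L)
  # empty inputs
  e <- associate(boxes(), trk, 0.3)
  expect_identical(e$unmatched_tracks, 1L)
  expect_length(e$unmatched_detections, 0)
})

test_that("associate attains brute-force optimal total IoU", {
  set.seed(5)
  for (k in 1:100) {
    n <- sample(0:6, 1); m <- sample(0:6, 1)
    trk <- random_box_matrix(n)
    det <- random_box_matrix(m)
    a <- associate(det, trk, 0)
    iomat <- iou_matrix(trk, det)
    got <- if (nrow(a$matches))
      sum(iomat[a$matches[, c("track", "detection"), drop = FALSE]])
    else 0
    expect_equal(got, brute_force_total_iou(iomat), tolerance = 1e-9)
    # partition invariant
    expect_setequal(c(a$matches[, "track"], a$unmatched_tracks), seq_len(n))
    expect_setequal(c(a$matches[, "detection"], a$unmatched_detections),
                    seq_len(m))
  }
})

test_that("step_tracks spawns, coasts, and deletes on max_age", {
  trk <- tracker_create(stand_config(max_age = 2))
  st <- step_tracks(trk, boxes(box(0, 0, 10, 10), box(50, 50, 70, 70)))
  expect_length(st$tracker$tracks, 2)
  expect_identical(vapply(st$tracker$tracks, `[[`, integer(1), "id"), 1:2)
  # starve the tracker: tracks survive exactly max_age unmatched frames
  trk <- st$tracker
  for (k in 1:2) {
    trk <- step_tracks(trk, boxes())$tracker
    expect_length(trk$tracks, 2)
  }
  trk <- step_tracks(trk, boxes())$tracker   # third unmatched frame
  expect_length(trk$tracks, 0)
  expect_identical(trk$n_deleted, 2L)
})

test_that("noise-free constant-velocity sequence keeps one identity", {
  stream <- constant_velocity_stream(10, c(50, 20), c(2, 6), 20, 24)
  trk <- tracker_create(cfg)
  ids <- integer(0)
  for (f in seq_along(stream)) {
    trk <- step_tracks(trk, stream[[f]])$tracker
    ids <- union(ids, vapply(trk$tracks, `[[`, integer(1), "id"))
  }
  expect_identical(ids, 1L)
  expect_identical(trk$n_created, 1L)
})

test_that("filter recovers the true velocity from noisy measurements", {
  set.seed(123)
  vel <- c(3, 5)
  w <- 30; h <- 40
  trk <- tracker_create(cfg)
  for (f in 0:30) {
    cx <- 50 + vel[1] * f + rnorm(1, 0, 1)
    cy <- 60 + vel[2] * f + rnorm(1, 0, 1)
    trk <- step_tracks(trk, boxes(box(cx - w / 2, cy - h / 2,
                                      cx + w / 2, cy + h / 2)))$tracker
  }
  expect_length(trk$tracks, 1)
  tr <- trk$tracks[[1]]
  se_u <- sqrt(tr$cov[5, 5]); se_v <- sqrt(tr$cov[6, 6])
  expect_lt(abs(tr$state[5] - vel[1]), 3 * se_u)
  expect_lt(abs(tr$state[6] - vel[2]), 3 * se_v)
})

test_that("created - deleted = live holds at every frame", {
  set.seed(31)
  scene <- generate_scene(scene_presets("V2", n_plants = 8, seed = 31,
                                        miss_prob = 0.3, fp_rate = 0.2))
  frames <- cornstand:::as_detection_stream(scene$detections)
  trk <- tracker_create(cfg)
  for (f in seq_along(frames)) {
    trk <- step_tracks(trk, frames[[f]])$tracker
    expect_identical(trk$n_created - trk$n_deleted,
                     length(trk$tracks))
  }
})
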
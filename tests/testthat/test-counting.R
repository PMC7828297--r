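test_that("check_crossing fires once per track on the trace segment", {
  line <- finish_line(0, 100, 200, 100)
  tr <- init_track(box(40, 90, 60, 100), 1L)
  tr$prev_center <- c(50, 95); tr$curr_center <- c(50, 105)
  ev <- check_crossing(tr, line)
  expect_identical(ev$track_id, 1L)
  # below the line: nothing
  tr$prev_center <- c(50, 80); tr$curr_center <- c(50, 90)
  expect_null(check_crossing(tr, line))
  # already counted: jittering back across does not re-fire
  tr$counted <- TRUE
  tr$prev_center <- c(50, 105); tr$curr_center <- c(50, 95)
  expect_null(check_crossing(tr, line))
  # fresh track with no history
  tr2 <- init_track(box(40, 90, 60, 110), 2L)
  expect_null(check_crossing(tr2, line))
})

test_that("five noise-free plants crossing the frame count as five", {
  cfg <- scene_presets("V3", n_plants = 5, seed = 2, miss_prob = 0,
                       fp_rate = 0, split_prob = 0, pos_noise_sd = 0,
                       ar_drift_sd = 0)
  scene <- generate_scene(cfg)
  res <- count_scene(scene)
  expect_identical(res$count, 5L)
  expect_identical(res$count, nrow(res$events))
  # one event per track id
  expect_identical(anyDuplicated(res$events$track_id), 0L)
})

test_that("a coasting track still crosses within its max_age grace", {
  # one plant at 15 px/frame toward a line at y = 90; detections stop at
  # center y = 70, so only the coasting prediction can cross. The box must
  # be tall enough (40 px) that consecutive-frame IoU clears the 0.3 gate.
  stream <- constant_velocity_stream(5, c(50, 10), c(0, 15), 30, 40)
  res <- run_pipeline(stream, finish_line(0, 90, 200, 90),
                      stand_config(max_age = 2), n_frames = 8)
  expect_identical(res$count, 1L)
  # with max_age 0 the track dies before reaching the line
  res0 <- run_pipeline(stream, finish_line(0, 90, 200, 90),
                       stand_config(max_age = 0), n_frames = 8)
  expect_identical(res0$count, 0L)
})

test_that("a single-frame false positive mid-field never counts", {
  stream <- constant_velocity_stream(12, c(50, 10), c(0, 12), 20, 20)
  with_fp <- stream
  with_fp[[5]] <- rbind(with_fp[[5]], box(150, 30, 170, 50))
  line <- finish_line(0, 120, 200, 120)
  expect_identical(run_pipeline(stream, line)$count,
                   run_pipeline(with_fp, line)$count)
})

test_that("count is invariant to uniform translation", {
  scene <- generate_scene(scene_presets("V2", n_plants = 10, seed = 17))
  base <- count_scene(scene)$count
  shift <- 37.5
  df <- scene$detections
  df[, c("x1", "x2")] <- df[, c("x1", "x2")] + shift
  df[, c("y1", "y2")] <- df[, c("y1", "y2")] + shift
  line <- scene$finish_line
  shifted_line <- finish_line(line[1, 1] + shift, line[1, 2] + shift,
                              line[2, 1] + shift, line[2, 2] + shift)
  res <- run_pipeline(df, shifted_line, n_frames = scene$n_frames)
  expect_identical(res$count, base)
})

test_that("count is invariant to detection order within frames", {
  scene <- generate_scene(scene_presets("V2", n_plants = 10, seed = 23))
  base <- count_scene(scene)$count
  set.seed(1)
  df <- scene$detections
  df <- df[sample(nrow(df)), , drop = FALSE]
  res <- run_pipeline(df, scene$finish_line, n_frames = scene$n_frames)
  expect_identical(res$count, base)
})

test_that("count is monotone over frames and matches the event log", {
  scene <- generate_scene(scene_presets("V2", n_plants = 6, seed = 4))
  res <- count_scene(scene)
  expect_identical(res$count, nrow(res$events))
  expect_true(all(diff(res$events$frame) >= 0))
})

test_that("malformed streams are rejected", {
  df <- data.frame(frame = c(-1L, 0L), x1 = c(0, 0), y1 = c(0, 0),
                   x2 = c(5, 5), y2 = c(5, 5))
  expect_error(run_pipeline(df, finish_line(0, 10, 10, 10)),
               "negative frame")
})
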
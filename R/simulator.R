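# Synthetic row-scene generator.
#
# Stands in for field video plus a trained detector: plants are laid out
# along a row and the camera cart's constant forward motion is modeled as
# scene translation along +y (plants enter at the top edge and flow toward
# a finish line near the bottom). Ground-truth trajectories have exactly
# constant velocity, so the tracker's motion model is satisfiable by
# construction; all difficulty comes from the detector noise model, which
# reproduces the observed failure taxonomy: missed detections, short-lived
# (1-2 frame) false positives such as weeds, one plant split into several
# stacked boxes, and aspect-ratio flutter from leaf motion.
#
# The paper-scale geometry behind the defaults: a ~0.8 m field of view
# mapped to a 1024 px frame and a cart at ~1 m/s filmed at ~30 FPS gives
# on the order of 12 px of scene motion per frame. Noise rates are the
# artifact's own desk-scale choices -- no field detector was measured.

#' Synthetic scene configuration
#'
#' @param n_plants Number of plants in the row.
#' @param frame_width,frame_height Frame size (px).
#' @param camera_speed Scene translation per frame along +y (px/frame).
#' @param spacing_mean,spacing_sd In-row plant spacing (px), mean and
#'   jitter.
#' @param box_w,box_h Base detection box size (px) for the growth stage.
#' @param size_jitter Relative per-plant size variation (uniform +/-).
#' @param pos_noise_sd Detection center noise sigma (px).
#' @param ar_drift_sd Per-frame sigma of the aspect-ratio random walk
#'   (reflected into `[0.3, 3]`, at constant area) emulating leaf flutter.
#' @param miss_prob Probability a visible plant is missed in a frame.
#' @param fp_rate Expected false-positive births per frame (Poisson); each
#'   false positive lives 1-2 frames and moves with the scene.
#' @param split_prob Probability a plant detection is split into 2-3
#'   vertically stacked fragments with 10% overlap.
#' @param seed Integer seed fixing the full scene.
#' @param stage Growth-stage label (`"V1"`-`"V4"`), informational.
#' @return List of class `scene_config`.
#' @export
scene_config <- function(n_plants = 20L,
                         frame_width = 1024, frame_height = 1024,
                         camera_speed = 12,
                         spacing_mean = 150, spacing_sd = 20,
                         box_w = 64, box_h = 72,
                         size_jitter = 0.1,
                         pos_noise_sd = 2,
                         ar_drift_sd = 0.02,
                         miss_prob = 0.1,
                         fp_rate = 0.05,
                         split_prob = 0.02,
                         seed = 1L,
                         stage = "V2") {
  stopifnot(n_plants >= 1, frame_width > 0, frame_height > 0,
            camera_speed > 0, spacing_mean > 0, spacing_sd >= 0,
            box_w > 0, box_h > 0, size_jitter >= 0, size_jitter < 1,
            pos_noise_sd >= 0, ar_drift_sd >= 0,
            miss_prob >= 0, miss_prob <= 1,
            fp_rate >= 0, split_prob >= 0, split_prob <= 1)
  structure(list(
    n_plants = as.integer(n_plants),
    frame_width = frame_width, frame_height = frame_height,
    camera_speed = camera_speed,
    spacing_mean = spacing_mean, spacing_sd = spacing_sd,
    box_w = box_w, box_h = box_h, size_jitter = size_jitter,
    pos_noise_sd = pos_noise_sd, ar_drift_sd = ar_drift_sd,
    miss_prob = miss_prob, fp_rate = fp_rate, split_prob = split_prob,
    seed = as.integer(seed), stage = stage
  ), class = "scene_config")
}

#' Growth-stage scene presets
#'
#' V1 seedlings are small relative to the position noise (tracking-hostile
#' small targets); V2 and V3 are the benign mid-season cases; V4 plants
#' are large with canopy overlap, so the detector splits them into parts
#' far more often. Numeric values are the package's own desk-scale
#' calibration, not field measurements.
#'
#' @param stage One of `"V1"`, `"V2"`, `"V3"`, `"V4"`.
#' @param ... Overrides passed on to [scene_config()].
#' @return A `scene_config`.
#' @export
scene_presets <- function(stage, ...) {
  presets <- list(
    V1 = list(box_w = 30, box_h = 36, pos_noise_sd = 3, ar_drift_sd = 0.03),
    V2 = list(box_w = 64, box_h = 72),
    V3 = list(box_w = 96, box_h = 104),
    V4 = list(box_w = 160, box_h = 168, split_prob = 0.15)
  )
  if (!is.character(stage) || length(stage) != 1L ||
      !stage %in% names(presets))
    stop("unknown growth stage: must be one of V1, V2, V3, V4",
         call. = FALSE)
  args <- utils::modifyList(c(presets[[stage]], list(stage = stage)),
                            list(...))
  do.call(scene_config, args)
}

reflect_into <- function(x, lo, hi) {
  width <- hi - lo
  while (x < lo || x > hi) {
    if (x < lo) x <- lo + (lo - x)
    if (x > hi) x <- hi - (x - hi)
  }
  x
}

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic scene
#'
#' Lays plants along the row with jittered spacing, translates them by the
#' camera speed every frame, and corrupts the per-frame ground truth into
#' detections with position noise, a per-plant aspect-ratio random walk at
#' constant area, missed detections, split detections, and short-lived
#' false positives. The number of frames is chosen so every plant fully
#' crosses the default finish line; fully reproducible from the seed.
#'
#' @param cfg A [scene_config()].
#' @return A `synthetic_scene`: list with `config`, `n_frames`,
#'   `finish_line` (the default line for the frame), `gt` (data frame
#'   `frame`, `id`, `x1`, `y1`, `x2`, `y2`, `conf`), `detections` (same
#'   columns, `id = -1`), and `true_count` (distinct plant ids whose
#'   center trace crosses the finish line).
#' @export
generate_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  with_seed(cfg$seed, generate_scene_impl(cfg))
}

generate_scene_impl <- function(cfg) {
  n <- cfg$n_plants
  w <- cfg$frame_width; h <- cfg$frame_height
  line <- default_finish_line(w, h)
  line_y <- line[1L, 2L]

  # plant layout: jittered spacing along the row, lateral scatter about
  # the row center, per-plant size variation
  spacing <- pmax(stats::rnorm(n, cfg$spacing_mean, cfg$spacing_sd),
                  cfg$spacing_mean / 5)
  plant_w <- cfg$box_w * (1 + stats::runif(n, -cfg$size_jitter, cfg$size_jitter))
  plant_h <- cfg$box_h * (1 + stats::runif(n, -cfg$size_jitter, cfg$size_jitter))
  plant_x <- w / 2 + stats::runif(n, -w / 6, w / 6)
  plant_y0 <- -cumsum(spacing) - max(plant_h)   # all start above the frame

  n_frames <- as.integer(ceiling((line_y - min(plant_y0) + max(plant_h)) /
                                   cfg$camera_speed) + 8L)

  # per-plant aspect-ratio random walks, one value per frame
  r0 <- plant_w / plant_h
  ar <- matrix(0, nrow = n, ncol = n_frames)
  for (i in seq_len(n)) {
    r <- r0[i]
    for (f in seq_len(n_frames)) {
      if (cfg$ar_drift_sd > 0)
        r <- reflect_into(r + stats::rnorm(1, 0, cfg$ar_drift_sd), 0.3, 3)
      ar[i, f] <- r
    }
  }

  gt_rows <- list()
  det_rows <- list()
  for (f in seq_len(n_frames)) {
    fy <- plant_y0 + cfg$camera_speed * (f - 1L)
    for (i in seq_len(n)) {
      cy <- fy[i]
      bx1 <- plant_x[i] - plant_w[i] / 2; bx2 <- plant_x[i] + plant_w[i] / 2
      by1 <- cy - plant_h[i] / 2; by2 <- cy + plant_h[i] / 2
      if (by2 < 0 || by1 > h) next   # not visible this frame
      gt_rows[[length(gt_rows) + 1L]] <-
        c(f - 1L, i, bx1, by1, bx2, by2, 1)
      if (stats::runif(1) < cfg$miss_prob) next
      # corrupted detection: center noise, aspect walk at constant area
      s <- plant_w[i] * plant_h[i]
      r <- ar[i, f]
      dw <- sqrt(s * r); dh <- sqrt(s / r)
      du <- plant_x[i] + stats::rnorm(1, 0, cfg$pos_noise_sd)
      dv <- cy + stats::rnorm(1, 0, cfg$pos_noise_sd)
      conf <- stats::runif(1, 0.6, 1)
      if (stats::runif(1) < cfg$split_prob) {
        k <- sample(2:3, 1L)
        frag_h <- dh / k
        ov <- 0.1 * frag_h
        for (q in seq_len(k)) {
          fy1 <- dv - dh / 2 + (q - 1L) * (frag_h - ov)
          fy2 <- fy1 + frag_h
          det_rows[[length(det_rows) + 1L]] <-
            c(f - 1L, -1L, du - dw / 2, fy1, du + dw / 2, fy2,
              stats::runif(1, 0.4, 0.8))
        }
      } else {
        det_rows[[length(det_rows) + 1L]] <-
          c(f - 1L, -1L, du - dw / 2, dv - dh / 2, du + dw / 2, dv + dh / 2,
            conf)
      }
    }
    # short-lived false positives (weeds, soil clutter); they sit in the
    # scene so they translate with the camera like everything else
    if (cfg$fp_rate > 0) {
      n_fp <- stats::rpois(1, cfg$fp_rate)
      for (q in seq_len(n_fp)) {
        life <- sample(1:2, 1L)
        fw <- cfg$box_w * stats::runif(1, 0.5, 1.2)
        fh <- cfg$box_h * stats::runif(1, 0.5, 1.2)
        fx <- stats::runif(1, 0, w)
        fy0 <- stats::runif(1, 0, h)
        for (l in seq_len(life)) {
          ff <- f - 1L + (l - 1L)
          if (ff >= n_frames) break
          yy <- fy0 + cfg$camera_speed * (l - 1L)
          det_rows[[length(det_rows) + 1L]] <-
            c(ff, -1L, fx - fw / 2, yy - fh / 2, fx + fw / 2, yy + fh / 2,
              stats::runif(1, 0.3, 0.7))
        }
      }
    }
  }

  to_df <- function(rows) {
    if (length(rows) == 0L)
      return(data.frame(frame = integer(0), id = integer(0),
                        x1 = numeric(0), y1 = numeric(0),
                        x2 = numeric(0), y2 = numeric(0), conf = numeric(0)))
    m <- do.call(rbind, rows)
    df <- data.frame(frame = as.integer(m[, 1L]), id = as.integer(m[, 2L]),
                     x1 = m[, 3L], y1 = m[, 4L], x2 = m[, 5L], y2 = m[, 6L],
                     conf = m[, 7L])
    df <- df[order(df$frame), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  gt <- to_df(gt_rows)
  det <- to_df(det_rows)

  # a plant is truly countable iff its center trace crosses the line
  # within the simulated frames
  crosses <- vapply(seq_len(n), function(i) {
    y_start <- plant_y0[i]
    y_end <- plant_y0[i] + cfg$camera_speed * (n_frames - 1L)
    segments_intersect(segment(c(plant_x[i], y_start), c(plant_x[i], y_end)),
                       line)
  }, logical(1))

  structure(list(
    config = cfg,
    n_frames = n_frames,
    finish_line = line,
    gt = gt,
    detections = det,
    true_count = sum(crosses)
  ), class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> stage %s: %d plants (true count %d), %d frames, %d detections\n",
    x$config$stage, x$config$n_plants, x$true_count, x$n_frames,
    nrow(x$detections)))
  invisible(x)
}

#' Run the counting pipeline on a synthetic scene
#'
#' Convenience wrapper: counts the scene's noisy detections against its
#' own finish line, padding to the scene's full frame range so coasting
#' tracks can finish crossing.
#'
#' @param scene A [generate_scene()] result.
#' @param config A [stand_config()].
#' @return A `count_result`.
#' @export
count_scene <- function(scene, config = stand_config()) {
  run_pipeline(scene$detections, scene$finish_line, config,
               n_frames = scene$n_frames)
}

#' Write a scene's detection and ground-truth files
#'
#' @param scene A [generate_scene()] result.
#' @param det_path Output path for the (noisy) detections, ids written
#'   as -1.
#' @param gt_path Optional output path for the ground truth with real
#'   plant ids.
#' @export
write_scene <- function(scene, det_path, gt_path = NULL) {
  write_detections(scene$detections, det_path)
  if (!is.null(gt_path)) write_detections(scene$gt, gt_path)
  invisible(scene)
}
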
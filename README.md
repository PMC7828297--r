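# cornstand

Early-season corn stand counting from video-style detection streams.

Breeders and geneticists need the number of emerged seedlings per row (the
*stand count*) to assess germination and population density, and manual
quadrat counts do not scale. When a camera is pushed along a crop row, a
per-frame object detector produces bounding boxes, but counting raw boxes
or raw track identities badly over-counts: detectors blink, re-detected
plants get fresh identities, and wind reshapes the boxes. `cornstand`
implements the tracking-by-detection counting pipeline that addresses
this:

- **Kalman tracking.** Each track carries the 8-component state
  `x = (u, v, s, r, u̇, v̇, ṡ, ṙ)` — box center, area, width/height aspect
  ratio, and their per-frame rates — under a discrete constant-velocity
  model. The aspect ratio is a *time-varying* state, so leaf flutter that
  reshapes a box is tracked rather than fought.
- **IoU-gated optimal assignment.** Detections are assigned to predicted
  tracks by the Hungarian algorithm maximizing total IoU; any assigned
  pair with IoU below a gate (default 0.3) is demoted to unmatched.
- **max-age lifecycle.** Unmatched tracks coast on prediction alone for up
  to `max_age` frames (default 2) before deletion; unmatched detections
  spawn new tracks.
- **Finish-line counting.** A track is counted exactly once, when the
  segment joining its consecutive centers crosses a fixed finish line
  (default: horizontal at 90% of frame height). Counting accuracy is
  scored as `(1 − |N_GT − N_M| / N_GT) × 100%`.

Because no trained detector ships with the package, a seeded synthetic
scene simulator stands in for field video: plants drift through the frame
at constant velocity (a cart at ~1 m/s) while the "detector" misses
plants, emits short-lived false positives (weeds), splits one plant into
stacked fragments, and lets aspect ratios random-walk. Growth-stage
presets `V1`–`V4` span small tracking-hostile seedlings to large
split-prone canopies. Evaluation utilities provide counting accuracy,
per-frame TP/FP/FN matching, and single-class average precision at a
fixed IoU threshold.

## Worked example

```r
library(cornstand)
cfg <- scene_presets("V2", n_plants = 10, seed = 42)
scene <- generate_scene(cfg)
print(scene)
res <- count_scene(scene)
print(res)
cat(sprintf("counting accuracy: %.2f%%\n",
            counting_accuracy(scene$true_count, res$count)))
ev <- evaluate_detections(scene$gt, scene$detections, iou_threshold = 0.5)
cat(sprintf("detection AP@IoU0.5: %.2f%% (TP %d, FP %d, FN %d)\n",
            ev$ap, ev$tp, ev$fp, ev$fn))
```

prints

```
<synthetic_scene> stage V2: 10 plants (true count 10), 232 frames, 864 detections
<count_result> count 10 over 232 frames (42 tracks created, 41 deleted, 1 live)
events (frame, track_id):
 frame track_id        x        y
    99        1 469.7604 932.2180
   110        4 489.3066 925.8623
   ...
   218       34 553.2112 929.0339
counting accuracy: 100.00%
detection AP@IoU0.5: 87.16% (TP 805, FP 59, FN 109)
```

Note what the numbers say: the noisy detector split and missed its way to
42 track identities over the run — counting identities would report 42
plants — yet exactly 10 tracks crossed the finish line, matching the
ground truth. The spurious 32 tracks were short-lived and expired before
reaching the line.

## Command line

```sh
Rscript inst/scripts/standcount-simulate --preset V2 --plants 30 --seed 1 \
    --out dets.txt --gt gt.txt
Rscript inst/scripts/standcount-count --detections dets.txt \
    --frame-size 1024x1024 --iou-threshold 0.3 --max-age 2 --out report.txt
Rscript inst/scripts/standcount-evaluate --pred dets.txt --gt gt.txt --iou 0.5
```

Detection files are MOT-style text: `frame,id,x,y,w,h,conf` with 0-based
frames and top-left + width/height boxes; the id field is `-1` for
anonymous detections and a real plant id in ground-truth files.

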
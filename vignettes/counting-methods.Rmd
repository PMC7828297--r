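---
title: "Stand counting by tracking-by-detection: model, parameters, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stand counting by tracking-by-detection: model, parameters, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cornstand)
```

## The problem

A camera pushed along a crop row at walking speed yields a video in which
every emerged seedling enters at one image edge, drifts across the frame
at the (near-constant) cart speed, and exits at the other edge. A
per-frame detector supplies axis-aligned bounding boxes with confidence
scores. The quantity of interest is the stand count: how many distinct
plants passed through the frame. Neither raw detections nor raw track
identities answer this — detectors miss plants for a few frames,
hallucinate short-lived boxes on weeds and soil, and split large plants
into parts; every such blink mints a fresh track identity, so identity
counts over-report badly. `cornstand` counts *finish-line crossings of
tracks* instead, which is robust to all of these failure modes as long as
spurious tracks are short-lived.

## State-space model

Each track carries the state

$$x = (u, v, s, r, \dot u, \dot v, \dot s, \dot r)^\top$$

with $(u, v)$ the box center (px), $s$ the box area (px²), $r$ the
width/height aspect ratio, and per-frame rates of change. The detector is
observed through $z = (u, v, s, r)^\top$. Two modeling choices matter:

- **Constant velocity with $\Delta t = 1$ frame.** The cart moves at
  near-constant speed, so inter-frame displacement is approximately
  constant. The transition matrix is identity plus a unit coupling from
  each rate to its component.
- **Aspect ratio as a state, not a constant.** Leaf flutter changes box
  shape at roughly constant area; carrying $\dot r$ lets the filter follow
  that drift instead of treating it as measurement noise.

The source of this design specifies the state but not the noise
covariances, so those are this package's own calibration, all exposed in
`stand_config()`:

| parameter | default | units | why |
|---|---|---|---|
| `process_noise_pos` | 1.0 | state units² / frame | small slack on measured components under near-constant velocity |
| `process_noise_rate` | 0.01 | state units² / frame | rates drift slowly (cart speed is steady) |
| `meas_noise` | (1, 1, 10, 0.01) | px², px², px⁴, — | px-scale center jitter; area noise scales with area; ratio is well measured |
| `init_rate_var_mult` | 1000 | — | rates are unobserved at birth; a vague prior lets the first updates set the velocity |
| `iou_threshold` | 0.3 | — | common tracking-by-detection gate |
| `max_age` | 2 | frames | best value reported for this task; see below |

The measurement update uses the Joseph-form covariance so the posterior
stays symmetric positive semidefinite even at extreme gains; this is
property-checked over 10,000 random steps in the acceptance suite. "High
uncertainty at initialization" is read here as a large prior on the
unobserved rates ($P_0$), not as inflated measurement noise; both knobs
are separately configurable.

## Association and lifecycle

Predicted track boxes are assigned to detections by the Hungarian
algorithm maximizing total IoU (cost $1 - \mathrm{IoU}$, rectangular
instances padded with a forbidden cost). The optimal assignment is then
*gated*: any assigned pair with IoU below the threshold is demoted to
unmatched on both sides, so the gate double-checks the association rather
than steering it. Ties between equal-affinity assignments are broken
toward low (track, detection) index pairs via an infinitesimal ($10^{-12}$
per index step) cost perturbation — deterministic, and far below any
meaningful IoU difference. No assignment-problem solver is available in
the supported dependency set, so the $O(n^3)$ potentials formulation is
implemented in-package and verified against a brute-force permutation
oracle on every run of the test suite.

Unmatched detections spawn tracks immediately — there is no minimum-hit
probation, by fidelity to the pipeline being reproduced. Unmatched tracks
coast on prediction alone and are deleted once `time_since_update`
exceeds `max_age`. Coasting tracks remain eligible for counting: that is
precisely the point of the grace period, since a plant whose detection
blinks out one frame before the line must still be counted.

## Counting

The finish line is a fixed segment, by default horizontal at 90% of frame
height — near the exit edge so tracks are mature when tested, with margin
so a coasting track can still reach it. At each frame, after the tracker
step, every live track whose segment between previous and current centers
intersects the line is counted and flagged; the flag is monotone, so a
track counts at most once regardless of jitter or crossing direction.
Intersection is the closed-segment orientation test; an endpoint exactly
on the line counts (deterministic, conservative tie-break). Counting is
tracker-driven: a never-matched track that survives to the line would
count — accepted because such tracks almost always expire first, which is
also the asserted behavior of the false-positive scenarios in the test
suite.

## The synthetic world

`generate_scene()` replaces field video plus trained detector. What it
emulates, and its defaults:

- **Geometry.** A 1024-px frame spanning ~0.8 m of row; a cart at ~1 m/s
  filmed at ~30 FPS gives ~12 px/frame of scene translation along +y.
  Plants are spaced 150 ± 20 px along the row with lateral scatter, and
  enter/exit through the frame edges. Ground-truth trajectories have
  *exactly* constant velocity, so the motion model is satisfiable by
  construction and every tracking failure is attributable to the noise
  model.
- **Detector noise** (per-plant-frame unless noted): miss probability
  0.1; false-positive births 0.05/frame (Poisson), each living 1–2 frames
  and translating with the scene; split probability 0.02, replacing a box
  by 2–3 vertically stacked fragments with 10% overlap; center noise
  σ = 2 px; aspect-ratio random walk σ = 0.02/frame, reflected into
  [0.3, 3] at constant area. These rates are the package's own desk-scale
  calibration — the reproduced pipeline reports no quantitative detector
  noise — and the robust-count benchmark built on them is labeled as the
  artifact's own, not a field claim.
- **Growth-stage presets.** `V1` small boxes (30×36 px) with σ = 3 px
  noise (high *relative* noise: the small-target-hostile case); `V2`/`V3`
  medium boxes; `V4` large boxes (160×168 px) with split probability
  0.15, encoding canopy overlap being carved into parts.

What it does **not** emulate: appearance (no pixels are rendered),
occlusion between neighboring plants, detector confidence correlated with
difficulty, camera vibration as autocorrelated noise, or row curvature. A
green exact-count test therefore establishes that the pipeline logic is
correct under its stated assumptions — not that any detector achieves
these noise rates in a field.

## Numerical choices and degenerate inputs

- Box ↔ measurement conversion is exact ($w = \sqrt{sr}$,
  $h = \sqrt{s/r}$); round-trip error is property-tested below 1e-9 px.
- A predicted state with non-positive $s$ or $r$ (overshoot on a shrinking
  box) is clamped to 1e-6 for geometry only; the filter state is not
  modified.
- Boxes touching along an edge have IoU 0 (area-based definition); a
  singular innovation covariance raises an error rather than producing a
  silent pseudo-inverse.
- Frames missing from a stream are processed as empty (predict-only)
  frames; negative frame indices are rejected.
- Counting accuracy is undefined at zero ground truth and errors.

## Known limitations

- Identity fragmentation under heavy relative jitter (the small-seedling
  case) is reproduced, not solved: when per-frame displacement is
  comparable to box size, the IoU gate starves tracks and the count
  degrades. This is asserted as a failure scenario, matching the behavior
  being reproduced.
- A single finish line counts one row; multi-row stitching, direction
  filtering, and side-view counting of late stages are out of scope.
- The Hungarian solver recomputes from scratch each frame; fine for tens
  of concurrent tracks, not tuned for hundreds.
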
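---
title: "Methods: weed segmentation and seedling-avoiding trajectory planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weed segmentation and seedling-avoiding trajectory planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(spotweed)
```

## The problem

Spot spraying of herbicide in a row crop needs three computations chained
together: find the weeds in a downward-looking RGB image while excluding the
crop plants (whose bounding boxes come from an upstream detector), move each
weed position into the robot frame, and drive the spray nozzle from one weed
to the next along a path that is short but never collides with the crop
seedling standing between them. `spotweed` implements that chain for a delta
parallel-arm sprayer, together with the box-level evaluation metrics used to
score the upstream detector and seeded synthetic scene generators that make
every stage testable without field data.

## Weed segmentation: ExG, Otsu, opening, connected-domain filtering

Vegetation is separated from soil with the excess-green index, per pixel

$$\mathrm{ExG} = 2G - R - B \in [-510, 510],$$

which is strongly positive on green foliage and near zero (or negative) on
brown soil. Because crop foliage is also green, the crop boxes are blanked to
black **before** the index is computed (`mask_crops()`), which keeps global
pixel coordinates intact — important because the weed positions feed the
robot-frame calibration downstream.

The signed map is min–max normalized to $[0,255]$ and thresholded by Otsu's
criterion (the gray level maximizing between-class variance, via EBImage);
the above-threshold class is the vegetation foreground. Two details are
deliberate choices rather than forced by the method:

* **Normalization.** The index is rescaled per image; clipping of negative
  values first is available (`clip_negative`) but off by default, since the
  negative tail carries contrast that helps the split on reddish soils.
* **Unimodal guard (`exg_floor`, default 20).** Otsu always splits the
  histogram, so on a vegetation-free image it bisects pure soil noise and
  reports half the field as foreground. The chain therefore additionally
  requires the *raw* index to exceed an absolute floor. Soil pixels sit near
  zero with a noise swing of roughly $\pm 4\sigma_c$ for per-channel noise
  $\sigma_c$, while sprayable vegetation is tens of units above; 20 is
  comfortably between the two for the contrast regime the chain is designed
  for (≥ 60 over the soil median). Setting `exg_floor = -Inf` recovers the
  plain Otsu split.

The binary mask is cleaned by morphological opening (erode, then dilate; 3×3
cross kernel, one iteration each) which removes sub-kernel specks while
changing large blob areas by only a few percent. Connected components are
labelled with **8-connectivity** — diagonal contact joins a component — and
components with pixel area below the **minimum connected domain size**
(`mcds`, default 50, inclusive: area ≥ mcds is retained) are discarded. Each
surviving component becomes one weed: its morphological centre is the mean
pixel coordinate, and its outer rectangle is the axis-aligned bounding box by
default, with a rotating-calipers minimum-area rectangle behind
`rect_mode = "rotated"`. Reported coordinates are 0-based pixels
(x = column, y = row); boxes are half-open.

```{r seg-demo}
scene <- gen_field_image(field_scene_config(width = 320, height = 320,
                                            n_weeds = 8, n_crops = 1,
                                            seed = 7))
seg <- segment_weeds(scene$image, scene$crop_boxes, seg_config(mcds = 50))
seg
```

Calibration to the robot frame is an affine map
(`pixel_to_robot()`): scale by `mm_per_px`, add the camera-origin offset and
the fixed advance the machine drives between imaging and spraying.

## The arch trajectory

One *weeding cycle* moves the nozzle from the current weed S to the next
weed E. The crop plant standing between them is idealized as a vertical
cylinder: standoff `w1` from S to the near footprint edge, radius `w2`,
height `h3`. Planning happens in the vertical plane through S and E
(`plane_embedding()` maps it to and from the robot frame); inside that plane
the path is an arch of five phases:

1. vertical ascent S → P0 of height `h1`;
2. cubic Bezier transition P0…P3 rising by `h2` to the apex height
   `h1 + h2`, ending above the near footprint edge, P3 = (w1, h1+h2);
3. horizontal pass P3 → P4 spanning the footprint at apex height;
4. mirrored Bezier transition P4…P5 descending;
5. vertical descent P5 → E.

The transition shape has two free offsets. P1 sits `alpha` above P0 (along
the ascent direction) and P2 sits `beta` back towards S from P3 (along the
horizontal). Bounding them by

$$0 \le \alpha \le 0.8\,h_2, \qquad 0 \le \beta \le 0.8\,(w_1 + w_2)$$

keeps the curve's curvature smooth at the junction with the horizontal
phase, so the arm does not vibrate when crossing it at speed. With both
offsets at zero the control polygon degenerates and the transition is the
straight chord — the shortest, but sharpest-cornered, member of the family.
The E-side transition mirrors the same offsets; the placement of P3 over the
near footprint edge and the mirrored construction are design choices (the
arch is drawn symmetric) and make the horizontal phase cover the footprint
exactly.

Feasibility is the *footprint-minimum* test: the path clears the crop iff
the minimum z over all polyline points with $u \in [w_1, w_1 + 2 w_2]$ is at
least $h_3$ plus the configured margin. This subsumes any single-point
clearance test and is what `check_clearance()` reports. A footprint outside
the S–E span is flagged and trivially feasible.

Numerics: each phase is sampled with `samples` points (default 200; phase
joints appear twice so each phase slice carries its endpoints — the
zero-length chords are harmless), path length is chord summation (no closed
form exists for cubic Bezier arc length; doubling the sampling changes the
length by well under 0.1 %), and curvature uses the analytic Bezier
derivatives. Offsets outside their bounds are an error in `build_arch()`;
the optimizer clips instead (below). Heights and distances are millimetres
throughout.

## Swarm optimization of the transition offsets

The planner searches the $(\alpha, \beta)$ box for the shortest feasible
arch. Fitness is the sampled path length, plus a large penalty
(`penalty = 1e6` mm) when the clearance test fails — a penalty method keeps
the swarm dynamics total, rather than rejecting infeasible particles. The
velocity update is the classic two-attractor rule

$$v \leftarrow \omega v + c_1 R_1 (\mathrm{pbest} - x) + c_2 R_2 (\mathrm{gbest} - x),$$

with fresh uniform draws per particle and dimension, followed by the
position update $x \leftarrow x + r\,v$ where

$$r(n) = 1 - \tanh\!\frac{n}{1 + n_{\max}}$$

is an adaptive factor equal to 1 at the first iteration and strictly
decreasing, so the position steps shrink as the search proceeds. Positions
are clipped to the box and the clipped component's velocity zeroed.
Particles start uniform over the box with zero velocity, under a seeded RNG:
identical seed, identical run.

Defaults: 5 particles and 200 iterations (the simulation regime the planner
is sized for); $\omega = 0.7$, $c_1 = c_2 = 1.5$ are standard swarm settings
— the problem is two-dimensional and mildly multimodal at worst, so the
optimizer's job is easy, and the package's tests tie its result to an
exhaustive `grid_oracle()` rather than to any particular constant choice.
The reference simulation scene (`reference_spray_scene()`) uses a crop
cylinder of height 150 mm whose centre stands 100 mm from S (`w1` = 60 mm,
so `w2` = 40 mm) and an apex of 170 mm. The apex split is `h1` = 20,
`h2` = 150 mm: the transition height then equals the crop height, which is
the natural reading of the cylinder-height convention, and only the sum is
constrained by the planning height.

```{r pso-demo}
plan <- optimize_transition(reference_spray_scene(),
                            swarm_config(seed = 1))
plan
```

An infeasible outcome (no particle ever cleared the crop) is returned as a
plan with `feasible = FALSE` plus a warning, never silently.

## Delta-arm kinematics and discretization

The spray nozzle rides a three-armed delta parallel manipulator. Inverse
kinematics solves, per arm (azimuths 0°, 120°, 240°), the circle–sphere
intersection in the arm's vertical plane and keeps the **knee-out** branch
(elbow farther from the central axis), the branch on which all three angles
grow monotonically as the target descends the axis. Forward kinematics — the
lower intersection of the three forearm spheres, by trilateration — serves
as the built-in consistency oracle: round trips close to below $10^{-6}$ mm.

No arm dimensions are fixed by the application, so the geometry is fully
parameterized with plausible bench-scale defaults (base radius 150 mm,
platform radius 50 mm, upper arm 200 mm, forearm 400 mm, base mounted
500 mm above the ground plane); every kinematic routine takes the geometry
as an argument and the tests are geometry-parameterized rather than
constant-baked.

For execution, the planned path is resampled into 100 points at **equal
arc-length spacing** (`discretize_trajectory()`), endpoints exact. Equal
steps along the path, rather than equal Bezier parameter, is what gives the
motors uniform pacing. The per-step difference of the three joint angles
between adjacent points (`joint_deltas()`) is the motor command stream; the
increments telescope exactly to the total angle change, and on the reference
scene at 100 points no step exceeds a few degrees — evidence that the IK
branch never flips along the path.

## Detection metrics

The upstream crop detector is scored with the usual single-class box
metrics: IoU on half-open pixel rectangles, greedy matching (predictions in
descending confidence, each taking the unmatched ground-truth box of highest
IoU ≥ threshold), and

$$\mathrm{precision} = \frac{TP}{TP + FP}, \qquad
  \mathrm{recall} = \frac{TP}{TP + FN},$$

reported in percent with half-up rounding to one decimal for display.
Average precision is the area under the monotone (all-point interpolated)
precision–recall envelope; the 0.5:0.05:0.95 threshold sweep gives the
strict mean AP. The all-point convention is a documented package choice —
evaluation frameworks differ (11-point, 101-point), and AP values are only
comparable within one convention, so the package's AP is not asserted
against any external AP figure, while precision/recall arithmetic is
convention-free.

## What the synthetic generators emulate — and what they do not

`gen_field_image()` renders a brown-dominant soil background with per-pixel
uniform noise, then places non-overlapping irregular blobs (ellipse-like
boundaries perturbed by low-order angular harmonics): green weed blobs with
controlled pixel areas, and larger crop blobs whose bounding boxes play the
role of the upstream detector's output. Vegetation colours are drawn so that
every vegetation pixel keeps a configured excess-green contrast (default
≥ 60) over the soil median even at the noise extremes — the regime the
segmentation chain assumes. Ground truth (areas, centroids, boxes) is
recorded from the drawn pixel sets, never re-measured from the rendered
image. Default sizes: 640 × 640 px, 30 weeds of 100–900 px, 3 crops —
a realistic working resolution and density for a single camera frame.

This emulates the geometry and radiometry the chain relies on. It does
**not** emulate photometric field pathologies: overexposure, specular soil,
shadows, adhering weed–crop clusters, or terrain tilt. A passing synthetic
recall therefore certifies the algorithmic chain (index, threshold,
morphology, area filter, centroid extraction), not field robustness under
those pathologies.

`gen_spray_scene()` draws weed-pair distances and cylinder parameters from
ranges that are feasible by construction (apex above plant, footprint
strictly between the weeds), resampling a bounded number of times.
`gen_detection_tables()` constructs box sets whose greedy matching yields
exact requested TP/FP/FN tallies, which lets the metric arithmetic be
exercised at the published operating points.

## Problem sizes used by the test suite

The suite runs the planner's 20-seed sweep on the reference scene against a
40 × 40 grid oracle, scores segmentation recall on 20 generated images
(600 weeds), and checks the kinematic round trips on a few hundred sampled
points — sizes chosen so the whole suite exercises every claim in under a
minute on a laptop core while keeping the stochastic margins wide (measured
recall sits near 100 % against the 95 % bar; the swarm lands within a
fraction of a percent of the grid optimum).

## Known limitations

* One crop obstacle per weeding cycle; several crops near one path are
  reduced to the nearest crop box (the flagged pipeline choice), and crop
  height is a configured constant — a top-down camera cannot measure it.
* The clearance test is sampled, not analytic; with 200 samples per phase
  the sampling gap is far below a millimetre for bench-scale scenes.
* The weed visiting order is nearest-neighbour, not an optimal tour.
* Metrics are single-class; multi-class mAP is out of scope.
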
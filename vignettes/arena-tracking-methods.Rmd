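---
title: "Methods: shape features, posture states and trajectory quality control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shape features, posture states and trajectory quality control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(arenatrack)
```

`arenatrack` quantifies the locomotion of several animals filmed from above
in a circular arena. This vignette explains the model behind each stage,
the tunable parameters and their defaults, what the synthetic generator
does and does not emulate, and the numerical choices made where the design
was genuinely open. It states no empirical result that the package's tests
do not themselves compute.

## From masks to features

The package starts where a segmentation backend ends: one binary mask per
animal per frame. Any backend honouring the `segment_video()` contract can
stand behind the pipeline; the built-in reference backend (per-frame Otsu
threshold, connected components filtered to an area range, identity
assignment by point-prompt-in-component on the annotation frame, forward
greedy nearest-centroid propagation under a maximum match distance of five
mean blob radii) exists so the entire pipeline runs and is tested without
a foundation model. A foundation-model adapter would add backward
propagation and a bounded inference-state window; those are adapter
concerns outside this package.

Per mask we compute the outer boundary of the largest 8-connected
component (Moore neighbour tracing), the shoelace area centroid of that
polygon, the pixel-count area converted with the squared scale factor
(mm px⁻¹, from `compute_scale_factor()` or supplied directly), and a
direct least-squares ellipse fit (stable Halir–Flusser solution of the
algebraic conic problem). Axes are reported as full lengths with
`major >= minor` enforced, orientation axial in `[0, 180)` degrees. The
axis ratio `R = major / minor >= 1` carries the posture signal. Masks with
several components keep the largest with a warning — collisions are a QC
problem, not a feature-extraction problem. Contours with fewer than five
points cannot support an ellipse and leave the frame's shape columns `NA`.

Coordinates follow the raster convention: x right, y down, origin at the
top-left pixel centre, frames and pixels 0-based. "Polygon size" in the
output is the pixel-count-derived mm² area (the mask is the measurement;
the polygon is its boundary).

## Posture: elongated vs bent

A crawling larva is extended (large R); a head-casting larva curls and its
fitted ellipse becomes rounder (small R). Because absolute R depends on
the individual, classification is per track: z-score the track's R series
(population s.d.; configurable to sample s.d.) and threshold at
`z_threshold = 0.8` s.d. The z-scores are computed over the raw track,
before QC excision, so that removing frames later cannot relabel the
survivors; they are also listed among the raw per-frame outputs.

The published rule is printed as "bent iff z >= 0.8", yet the geometry
above implies a bent body sits in the *low* tail of R. The classifier
therefore exposes `bent_direction`: `"above"` (the default, exactly as
printed) or `"below"` (the geometric reading). The synthetic generator
separates the two R modes well enough that the conventions are empirically
distinguishable, and all synthetic-scene analyses in the tests use
`"below"` — on generator scenes the printed default would label the
elongated tail as bent. On real data the user should confirm the direction
once against a handful of frames (the z-scored overlays make this a
one-glance check) and set the switch accordingly; no code change needed.

## Trajectory quality control

Six failure modes of mask-propagation trackers are detected, in a fixed
order, each rule user-configurable in `qc_config()` and each comparison a
*strict* inequality:

1. **Static size** (`static_run_min = 20` frames): a track locked onto
   static background has exactly constant size. Runs of identical sizes
   longer than the limit are flagged. Equality is evaluated on raw pixel
   counts, not on derived mm² floats.
2. **Segmenting and infilling** (`infill_radius = 20`): maximal runs of
   flagged/unflagged frames form outlier/inlier segments; an inlier frame
   within the radius of *both* a preceding and a following outlier segment
   is re-flagged. Leading/trailing inlier segments are never infilled. The
   infill pass runs after the static stage and again after duplicate
   resolution (the final combined flag state); this placement follows the
   written pipeline order, noting that re-running it after every stage
   would be a defensible alternative.
3. **Size jumps** (`jump_threshold = 1.5` mm²): collision merges double
   the apparent body; any frame-to-frame area step larger than the
   threshold is flagged.
4. **Size drift** (`drift_median_kernel = 201`, `drift_smooth_kernel =
   11`, `drift_window = 80`, `drift_fraction = 0.75`, `drift_min_delta =
   1` mm²): during prolonged contact an identity can creep between
   animals. The size series is median filtered (kernel clamped to the
   largest odd value not exceeding the track length; reflect padding),
   differenced, and the difference smoothed; any 80-frame window in which
   at least 75% of entries share one strict sign is a candidate;
   overlapping candidates merge, and a merged segment is kept as flagged
   only if the filtered size changes by more than 1 mm² start to end —
   segments failing that magnitude check are un-flagged, since the check
   exists to confirm the drift is material. The thresholds
   `drift_min_delta` and `segment_median_delta` are printed bare (">1") in
   the source description; they are interpreted in mm², the unit of the
   size signal that the 1.5 mm² jump rule anchors.
5. **Identity switches** (`baseline_min_frames = 200`,
   `segment_median_delta = 1` mm²): the first inlier segment of at least
   200 frames sets a baseline median size (if none qualifies the stage
   logs a notice and is skipped); every other inlier segment whose median
   deviates by more than the delta is flagged wholesale.
6. **Statistical outliers** (`size_sd_limit = 4`, `speed_sd_limit = 5`):
   moments are estimated over the currently-inlier frames only, so
   corruption caught earlier cannot inflate the s.d.; inlier frames beyond
   the limits are flagged. The source material quotes ±4 s.d. for speed in
   one place and ±5 in the pipeline description; the default follows the
   more specific pipeline value (5), configurable. Zero-variance signals
   flag nothing, and a value at exactly the limit is *not* flagged.

After the per-track stages, **duplicate tracks** are resolved pairwise:
centroids identical within `duplicate_match_tol_px = 0.5` px (exact
identity is too fragile for floats) for more than `duplicate_min_frames =
100` frames mark a duplicate pair; the member with more outlier frames is
removed, ties keeping the lower (first) object id. The matched region,
widened by the infill radius, is flagged `duplicate` on the removed track,
which is dropped from the retained output and listed in the report.

Frames partition exactly into good and problematic per track; a track with
more than `omit_fraction = 1/3` flagged frames carries an omission
recommendation in the summary, leaving the decision to the analyst.

## Movement metrics

Displacement is the Euclidean centroid step between consecutive frames
times the scale factor (frame 0 contributes 0); speed multiplies by fps.
Aggregation over the good frames deliberately does **not** bridge gaps
left by excision: distance only accrues between temporally consecutive
retained frames, so removing frames can only shorten a track — consistent
with excision-based error handling, which trades data volume for validity.
(Bridging would instead interpolate across excised intervals; it is not
offered because it would fabricate path where the tracker failed.) Mean
speed is the mean of the retained per-frame speeds, including frame 0's
conventional zero — negligible at thousands of frames, documented here
because it differs from distance/total-time once frames are removed.
State-resolved variants restrict sums and means to elongated frames, and
body length — the median elongated-frame ellipse major axis, an
approximation chosen because "length" is otherwise undefined for a bending
animal — normalises distance and speed into body lengths for organisms of
unequal size.

Frame-rate reduction (`downsample_fps()`, every round(source/target)-th
frame from frame 0) exists because ~30 fps recordings oversample slow
crawling: centroid jitter accumulates into spurious path length, so
downsampling to ~10 fps shortens measured distance slightly and removes
processing overhead.

## The synthetic world

`scene_spec()` states the recording the pipeline was designed around: five
late-third-instar larvae in a 60 mm circular arena, 3 minutes at 10 fps,
0.1 mm px⁻¹ (the arena filling a ~600 px frame, as in a 720p recording).
Each animal is an elliptical blob (4 × 1 mm at rest, area ≈ 3.1 mm²)
driven by a first-order Markov chain over run/cast/pause states — runs
crawl at 0.8 mm s⁻¹ with a heading random walk, casts are slow and bent
(mean R 2.2 vs 4.0 elongated, well separated), pauses stand still. The
transition matrix defaults give mean dwell times of ~2 s (run), ~0.7 s
(cast) and ~1.2 s (pause) and a stationary bent fraction near 15–20%.
Animals reflect off the arena wall and softly repel within two body
lengths, so default scenes are collision-free — a deliberate property,
since the package's error handling is excision, not collision resolution.

A peristaltic oscillation (1.1 Hz, 2.5% length amplitude, 1.5% area
amplitude) modulates the body, at full amplitude during runs (it *is* the
stride cycle) and residual amplitude during casts and pauses. This detail
is load-bearing: without it a genuinely paused animal renders as a frozen
mask, which is byte-identical to the detached-track failure signature, and
the static-size rule would rightly flag it. Conversely the renderer draws
the *true* body, not the noisy measured one — measurement noise must come
out of rasterisation and segmentation, as in a real imaging chain,
otherwise it is counted twice and paused centroids random-walk.

What the generator does **not** emulate: biomechanical peristalsis wave
propagation, photorealistic texture and lighting, soft mask edges of a
learned segmenter, partial occlusion, and genuine collisions (injected
failures stand in for their *signatures* instead). A green end-to-end test
therefore establishes that the pipeline recovers what this idealised but
calibrated world defines — distance, posture fractions, clean QC — not
that any particular foundation model segments real video well.

Failure injection corrupts observation tables with the six signatures at
magnitudes that satisfy the corresponding trigger conditions by a
realistic margin (frozen 50-frame runs; +2 mm² steps; 2 mm² ramps over 200
frames, held afterwards — an identity that crept onto another animal stays
there; 300-frame switched segments with a 10 mm centroid displacement;
8 mm two-frame teleports; 150-frame centroid copies). Detection is scored
per event — an event counts as detected when at least half of its frames
carry any QC flag, matching how curated failure cases would be adjudicated
track by track — with the 50% overlap configurable.

## Numerical choices and degenerate inputs

* Median filter and moving average use reflect padding; kernels clamp to
  the largest odd length not exceeding the series.
* Tracks shorter than the drift window skip the drift stage with a logged
  notice; tracks without a 200-frame baseline segment skip the switch
  stage likewise.
* Zero-variance z-scores are defined as 0 (a constant-shape track is all
  elongated under the default convention).
* Degenerate (zero-area) polygons fall back to the vertex mean with a
  warning; empty masks, coincident calibration points and sub-5-point
  contours raise named errors.
* The duplicate tie-break (equal outlier counts) keeps the lower id,
  making resolution deterministic; the whole pipeline is deterministic
  given a seed, and stage order is fixed by design rather than
  configurable.

## Known limitations

Excision, not resolution: merged animals are flagged and removed, never
re-split. The reference backend propagates forward only and will lose an
identity that teleports beyond five blob radii between frames (downstream
QC then sees the gap). Video container decoding is delegated to the
backend adapter; within this package videos are in-memory or lazily
rendered frame stacks, and the annotated tracking output is a PNG frame
sequence rather than an encoded MP4. Left/right cast discrimination,
per-cast speed, angular velocity and inter-individual distance are out of
scope.
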
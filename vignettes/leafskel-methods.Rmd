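---
title: "Training-free leaf skeletonization: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training-free leaf skeletonization: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 6)
library(leafskel)
```

## The problem and the approach

Geometric leaf phenotypes — how many leaves a potted plant has, how wide
its crown spreads, how uniform its leaves are in length, angular
distribution and height — are routinely read off a *skeleton*: one
centreline polyline per leaf. Learning-based skeletonizers need annotated
keypoints and training runs, and classical thinning or medial-axis
transforms inherit every defect of the binary mask as spurious branches.
`leafskel` implements a third route that needs neither labels nor
training: sample random interior points on the segmented leaf area, then
*connect* them greedily into one polyline per leaf under simple geometric
rules. Two connection rules cover the two canonical leaf habits:

* **random morphology** (top view, leaves radiating at arbitrary
  azimuths): an angle-difference rule. After the first two keypoints fix
  a direction, each next keypoint is the candidate whose turning angle
  differs least from the previous turning angle, accepted only if that
  difference is at most `theta_max` (20 degrees). This tracks smoothly
  bending midribs while refusing sharp turns onto neighbouring leaves.
* **regular morphology** (front view, leaves arching under gravity): a
  convexity / curvature-minimization rule. Consecutive keypoint triples
  must pass the *arch test* — the middle vertex may not fall below the
  chord of its neighbours — and where two continuations are admissible
  the flatter one (smaller turning angle, or a later candidate lying
  above the current tentative point) wins.

Both tracers search for the next keypoint in a circular region that
starts small (`r0` = 5 px) and expands stepwise until an admissible
candidate appears, and both halve the search space using the dominant
axis of the current motion (the half-plane rule). A trace ends when its
exhausted search circle touches the pot circle (top view) or the bottom
reference line (front view) — the leaf has reached its base — or when
the radius cap is hit.

## Pipeline stages

`run_pipeline()` chains four stages, each available on its own:

1. **Segmentation** (`segment_plant()`): HSV hue thresholding (green
   window 35–85 degrees) with saturation/value floors, morphological
   closing then opening with a 5×5 box kernel, connected-component
   analysis, and two contour filters — area ≥ 500 px² and minimum-area
   bounding-rectangle aspect ratio strictly greater than 2 (leaves are
   elongated; pots, labels and blobs are not). The pot circle is centred
   on the leaf-mask centroid with radius half the "length" of the
   shortest retained contour; the front view instead estimates the
   bottom reference line from the pot's top edge.
2. **Sampling** (`erode_boundary()`, `stratified_sample()`): one
   5×5 erosion pulls the mask away from leaf edges so samples hug the
   midrib, then a 40×40 grid over the image draws exactly one uniform
   pixel per cell with eligible foreground (pot interior excluded in top
   view). All randomness flows through one integer seed.
3. **Tracing** (`trace_all()`): the outer loop repeatedly takes the
   unvisited point farthest from the anchor (pot centre / plant base) as
   the next leaf tip and runs the view-appropriate tracer. Accepted
   keypoints are marked visited; leftover points within `consume_width`
   of the accepted polyline are retired so they cannot seed duplicate
   leaves. Traces shorter than `min_keypoints` are dropped.
4. **Phenotypes** (`phenotype_report()`): leaf count; crown width (max
   pairwise tip distance) and its ratio to the pot diameter; leaf length
   consistency (population variance of per-leaf arc lengths); leaf
   distribution consistency (Gaussian-weighted variance of the arc
   lengths cut on concentric rings between pot and crown circle); leaf
   height consistency (variance across leaves of the mean keypoint
   height above the reference line).

```{r pipeline-demo}
plant <- make_plant_top(8, rng_seed = 1)
res <- run_pipeline(plant$image, view = "top")
res$skeleton
res$phenotypes
```

```{r autoplot-demo}
autoplot(res$skeleton)
```

## Parameters

The segmentation/sampling/threshold constants form one fixed set used
for every image; they are exposed in `pipeline_config()` but changing
them should be the exception, not the rule.

| key | default | unit | role |
|---|---|---|---|
| `hue_min`, `hue_max` | 35, 85 | degrees | green hue window |
| `sat_min`, `val_min` | 40, 40 | 0–255 | floors; grey/black pixels have no meaningful hue |
| `kernel_side` | 5 | px | closing/opening/erosion box kernel |
| `erosion_iterations` | 1 | — | boundary pull-back before sampling |
| `area_min` | 500 | px² | contour area cut-off |
| `ar_min` | 2 | — | bounding-rect aspect-ratio filter (strict) |
| `grid` | 40 | cells/side | stratified sampling lattice |
| `r0` | 5 | px | initial search radius |
| `theta_max` | 20 | degrees | angle-difference threshold (inclusive) |

The remaining keys are this implementation's own plumbing:

* `r_step` (= `r0`) — radius growth per expansion; the sources only say
  the circle is "iteratively expanded".
* `r_max` (image diagonal / 4) — cap preventing unbounded expansion over
  sparse regions; reaching it ends the trace like the base rules do.
* `min_keypoints` (3) — a polyline shorter than one triple carries no
  angle or convexity information.
* `consume_width` (8 px) — the post-trace retirement corridor. It should
  be at least the half-width of a leaf after erosion: narrower corridors
  leave stray points mid-leaf that re-seed as spurious "leaves" whose
  tips sit in the middle of an already-traced blade.
* `arch_tol` (3 px) — perpendicular slack of the arch test, discussed
  below.
* `n_rings` (9) and `sigma` (`n_rings / 4`) — ring count and Gaussian
  width for the distribution phenotype. Any positive `sigma` preserves
  the intended mid-radius emphasis; `sigma → ∞` weights all rings
  equally.
* `halfplane_mode` (`"axis"`) — the literal axis-aligned reading of the
  direction rule; `"vector"` restricts to the half-plane normal to the
  motion vector instead.
* `pot_radius_mode` (`"rect"`) — a contour's "length" is read as the
  longer side of its minimum-area bounding rectangle (a leaf's length).
  The perimeter reading (`"perimeter"`) is also available but roughly
  doubles the radius, since a thin leaf's perimeter is about twice its
  length.

## Numerical choices

**Population variance.** All consistency phenotypes divide by *n*, so a
single leaf yields 0, not `NA`.

**Angle units.** Search rules compare angles in degrees with inclusive
thresholds. Discrete curvature uses interior angles in radians so that
its unit is 1/px, commensurable with the analytic curvature
`|y''| / (1 + y'^2)^(3/2)`, and so that a straight polyline has exactly
zero curvature. The printed discrete form is a second difference of
interior angles over the local edge lengths; its magnitude is reported
(a signed variant sits behind `signed = TRUE`).

**Tie-breaks.** Wherever two candidates score equally the smaller
Euclidean distance wins, then the smaller row, then the smaller column.
This makes every stage a deterministic function of the seed.

**Arch-test tolerance.** The convexity constraint is exact in the
limit of dense, noise-free midrib samples. Grid-stratified sampling,
however, places each keypoint anywhere within the eroded leaf width, so
keypoints carry a lateral noise of a few pixels, while the true convex
sag between neighbouring keypoints at working resolution is an order of
magnitude smaller. An exact test therefore rejects most genuine
continuations. `arch_tol` (default 3 px) allows the middle vertex to dip
up to that perpendicular distance below the chord; `arch_tol = 0`
restores the exact test. The same tolerance is used when validating
outputs.

**Degenerate inputs.** An empty mask after refinement, or a mask whose
every contour fails the filters, raises a typed condition
(`leafskel_empty_mask`); a pipeline that traces no leaf raises
`leafskel_no_leaves`. The CLI maps these to distinct exit codes.

## What the synthetic generator emulates — and what it does not

`make_plant_top()` renders leaves radiating from the pot rim with
parabolic midribs in each leaf's local frame; `make_plant_front()`
renders blade-shaped leaves fanning up from behind the pot rim, each a
segment of a convex `row(col)` parabola, so every ground-truth triple
passes the arch test by construction. Ground truth (midrib curves with
exact derivatives, tips, counts, crown width, pot, reference line, leaf
mask) is recorded before rendering, and rendering is bit-reproducible
per seed.

Deliberate features of real data that the generator reproduces:

* narrow tips — the half-width tapers to ~1 px, so boundary erosion
  eats the outermost tip, the cause of the tip-miss phenomenon
  (`tip_miss()` quantifies it);
* a hue-neutral grey background and a brown pot, so the HSV window, the
  saturation/value floors, and the pot detection all do real work;
* a "hard" top-view mode adding green speckles (removed by opening and
  the area filter) and a square green blob (removed by the
  aspect-ratio filter);
* mild/heavy angular jitter so neighbouring leaves approach or cross.

Features it does **not** model: specular highlights and illumination
gradients, shadows, serrated or lobed leaf outlines, overlapping plants,
perspective distortion, and sensor noise. Passing the bundled tests
therefore demonstrates the correctness of the geometry and of the
connection rules under controlled conditions — it does not certify
segmentation robustness on field imagery.

Generator geometry is chosen once to be realistic at desk scale: square
images of 560 px, a 55 px pot, top-view leaves of half-width 6 px and
lengths around 130–200 px, front-view blades of half-width 5 px with
inner leaves taller and steeper than outer ones so midribs provably
never cross. At a 40×40 sampling grid this gives cells of 14 px and a
lateral sampling noise of roughly ±4 px — about the ratio a
3000-px-wide orchid image with finger-wide leaves exhibits. The
front-view bases merge below the pot rim, as in a real pot, and are
occluded by it, so each visible blade is a separate elongated component
that survives the aspect-ratio filter.

## Design choices where the design was genuinely open

* **Search direction per step.** The half-plane is recomputed from the
  last two accepted keypoints at every step (not fixed per leaf), so
  the restriction follows a bending midrib. It applies to both
  morphologies.
* **Candidate sets.** "Candidates" are all unvisited points inside the
  current search circle and half-plane, not a fixed count; the
  front-view searches prefer at least two candidates before deciding
  (matching the intent of weighing alternatives) but settle for one at
  the radius cap.
* **Base termination.** The stop rule — an exhausted circle touching
  the pot circle — is evaluated whenever a radius yields no admissible
  candidate, not only when the circle is literally empty. Stray
  unvisited points near the base otherwise keep the circle formally
  non-empty while the radius balloons until the trace jumps across the
  pot onto the opposite leaf. The front view uses the analogous rule
  against the reference line.
* **Retry on a doomed start.** On fine grids the closest point to a tip
  can sit perpendicular to the leaf axis (two sampling bands inside one
  leaf), which fixes a perpendicular initial direction and kills the
  trace at two points. A discarded trace is retried from the same tip
  with that second point masked, up to three times, before the tip is
  given up.
* **Rejected candidates** stay available to later leaves; only accepted
  keypoints and the consumption corridor are retired.
* **Evaluation frames.** Curvature error compares the discrete
  curvature of a predicted polyline against an analytic curve `y(x)`.
  Top-view midribs are not functions of image x, so each leaf is scored
  in its own frame (origin at the base, x along the initial direction);
  external ground truth given as dense points is differentiated by
  local quadratic fits.

## Problem sizes used by the bundled checks

The test-suite and the acceptance script work at sizes chosen to give
stable statistics while staying comfortable on a single CPU: 20
synthetic plants per view (5–12 leaves, alternating clean and mild
overlap), 560 px images, and 200 random point sets of at most 12 points
for the tracer-versus-reference comparison. At these sizes a full
pipeline run takes well under a second per image.

## Known limitations

* Leaf recall above 100% is possible and does occur: a kink accepted by
  the angle-difference rule constrains the next step to a turning-angle
  band the true midrib may leave, the trace stops, and the leaf's
  remainder is traced as a second "leaf". Split leaves are inherent to
  the greedy rules (wide-bladed crops show the same behaviour) and are
  reported honestly rather than clipped.
* The aspect-ratio filter deletes genuinely compact leaf arrangements:
  a merged pair of crossing leaves can form a nearly square component
  and vanish. This mirrors the documented filter, not a defect of the
  implementation.
* Relative crown width inherits the pot-radius estimate (half the
  shortest contour length); plants whose shortest leaf is much shorter
  than the pot diameter overestimate the ratio.
* Phenotypes are in pixels; no camera calibration, hence no millimetre
  conversion.
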
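---
title: "Top-view depth-frame fall detection: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Top-view depth-frame fall detection: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depthfall)
```

## The sensing model

A depth camera is mounted on the ceiling, facing straight down from
`max_height` = 3000 mm.  Every frame is a 320×240 grid of distances in
millimetres from the sensor plane to the nearest surface; the floor reads
`max_height`, a standing adult's head about `max_height − 1700`.  Pixels
the sensor cannot resolve (corners, shadows, dark materials) carry the
null value 0.  The field of view spans ±28.5° along the 320-pixel axis
and ±21.5° along the 240-pixel axis, which fixes the pinhole conversion
between pixel segments and real lengths used throughout:

$$W_r = 2\,d\tan(28.5^\circ)\,\frac{W_p}{320}$$

horizontally, the analogous expression with 240 and 21.5° vertically, and
the Pythagorean combination of the two for diagonal segments (each
diagonal step advances one row *and* one column, so the same `Wp` enters
both terms).  `pixel_to_mm()` implements exactly this; one of the test
suites asserts the diagonal identity to 10⁻⁹ relative error and the exact
linearity in both arguments.

The top view trades body articulation for robustness: people appear as a
head cap above a shoulder slab, furniture as static slabs, and occlusion
is rare.  Everything downstream leans on that geometry.

## The processing chain and its parameters

| parameter | default | unit | role |
|---|---|---|---|
| `max_height` | 3000 | mm | sensor-to-floor distance |
| `floor_band` | 200 | mm | clamp-to-floor band |
| `th_person` | 50 | mm | foreground deviation threshold |
| `gap_coeff` | 6000 | mm | depth-level slicing constant |
| `th_sobel` | 2000 | — | gradient magnitude for edge carving |
| `head_drop_range` | [200, 300] | mm | head-over-shoulder drop window |
| `head_diag_range` | [200, 400] | mm | admissible head extent |
| `min_drop_directions` | 2 | — | directions required for the drop |
| `head_comparability_ratio` | 1.5 | — | max/min head-extent ratio |
| `fall_threshold` | 400 | mm | strict fall height rule |
| `fusion_split_radius` | 5 | super-pixels | carve radius around a peak |
| `track_grace` | 15 | frames | unmatched frames before retirement |

The `floor_band` absorbs carpet texture and near-floor limbs — a standing
person's feet are deliberately clamped away, which is why blobs are
shoulder-and-head shapes.  `th_person` must exceed sensor noise (the
simulator's ±5 mm) by a safe margin; `gap_coeff` only needs to be large
enough that a person/furniture boundary always carries a gradient above
`th_sobel`, whatever the raw depth difference.  With the L1 Sobel
magnitude |Gx|+|Gy| used here (chosen for integer exactness; the
threshold is calibrated to it), a sliced boundary carries at least
4·`gap_coeff` ≫ `th_sobel`, while a ±5 mm noise field stays around 80.

A super-pixel is occupied only if **all** 48 pixels of its block are
off-floor.  This conservative rule, combined with the one-pixel erosion
that edge carving applies to every object outline, is what separates
touching elements at the 40×40 resolution: a carved line through a block
empties it.

## The blob labeler

`distinguish_objects()` is a single-pass, run-based labeler: each row is
split into maximal runs of occupied cells, and every run is matched to
the previous row's runs by column overlap (the bitwise-AND of occupancy
vectors).  A run overlapping no previous object starts a new id; one
overlapping a single object continues it; one bridging several
previously distinct objects triggers the *side-effect merge* — the
outstretched-arms case, where two arm columns and the torso meet at one
row.  The survivor is the smallest id involved, remaining ids are
recompacted, and the merge applies equally to three or more collapsing
parts.  The partition provably equals 4-connected components; the test
suite checks 500 random grids against an independent flood-fill oracle
(igraph components over the 4-adjacency graph).  Diagonal-only contact
does **not** join blobs — exactly what the row-overlap rule implements.

Discovery order is part of the contract: ids are ordered by first
row-major occurrence, and each object's cells keep the order in which
the scan found them (the `ord` column), so merges can preserve it.

## Person identification

All three anthropometric checks start from the blob's *peak point* `mp`:
the depth minimum, averaged over the pixels within a planar radius of
100 mm and a depth window of 50 mm of that minimum.  The averaging radii
are the package's own choice (the underlying idea is only "average near
the maximum height"): 100 mm keeps the average on the head cap for adult
head sizes while shrugging off single-pixel noise; both are configurable
(`peak_radius`, `peak_depth_window`).

From `mp`, eight single-pixel scans (N, NE, …, NW) record consecutive
depth differences:

* **head–ground gap**: some direction contains a single step ≥ half the
  depth at `mp`.  Low furniture cannot produce it: a 750 mm desk's edge
  steps 750 mm, well under half its 2250 mm depth.
* **head–shoulder gap**: the *cumulative* drop from `mp` first lands
  inside 200–300 mm (head height above shoulders) in at least two
  directions.  Cumulative rather than single-step, because on a smooth
  head cap the drop accrues over several pixels; a drop that jumps
  straight past the window (head straight to floor, no shoulder) does
  not count.  The single-step reading is kept for the head–ground check,
  where the silhouette edge genuinely is one step.
* **head dimensions**: per direction, the head boundary is the distance
  at which either gap condition is first verified — or the distance to
  the frame border when neither is, which deliberately poisons the sum
  for blobs that are not head-like.  Opposite directions are summed into
  four extents (N+S, NE+SW, E+W, SE+NW), converted to millimetres at the
  peak's depth, and must all lie in 200–400 mm.  "Comparable to each
  other" is quantified as max/min ≤ 1.5 — a testable surrogate for an
  otherwise unquantified criterion.

A person is a blob passing all three.  On the simulator's scenes this
separates people from desks, chairs and floor clutter perfectly, and the
decision is invariant under horizontal mirroring (a property test).

## Tracking, fusions, falls

Tracking is containment-based, not nearest-neighbour: a person recognised
at frame *k−1* is placed into frame *k* at its stored central
super-pixel, and the blob containing that point carries the identity on.
Each blob's tracked content is classified: **A** (no person, at most one
object — run the person check, promote or record an object), **B** (one
person, no object — refresh the person's anchors on the new shape), or
**C** (anything else — a fusion).

Fusions are resolved by restricting the blob to the cells within a
Chebyshev radius of each participant's peak super-pixel and re-labeling
the restriction; each participant keeps the component containing its
peak.  Three design choices here are the package's own:

* the radius (5 super-pixels ≈ 300–400 mm at typical body depths) covers
  one torso, not two, and is configurable;
* cells inside several participants' radii go to the nearer peak (ties
  to the earlier participant) — the discard rule alone leaves contested
  cells unresolved;
* the split output is **re-validated**: a person's sub-blob must still
  pass the person check to carry the track on.  This is what makes the
  degraded-reference behaviour come out right: when a lying body merges
  with a desk, the merged material fails the head checks, the track
  starves, and after `track_grace` unmatched frames (0.5 s at 30 fps)
  the person is retired rather than mis-anchored — the fall goes
  unreported, and the subject is re-acquired as a new person on getting
  up.  Two upright people in shoulder contact, by contrast, both pass
  and both ids survive the fusion interval.

Objects are *not* re-anchored through fusion splits: updating a static
object's anchors onto moving fused cells lets stale object tracks ride a
walking person and turn plain tracking frames into spurious fusions.  An
object updates only when it sits alone in a condition-A blob; otherwise
it waits, and retires past the grace period.

A fall is a tracked person whose central-point height,
`max_height − CF(cp)`, drops **strictly below** 400 mm — the measured
thickness of a lying body.  Events are edge-triggered (one per excursion
below the threshold, re-armed on rising above it), with the per-frame
below-threshold flags also kept for height-trace plots.  Only persons
matched in the current frame are measured; a stale anchor would read the
floor and fire a false alarm the moment someone leaves the view.

## The simulator

`render_frame()` ray-casts a perspective projection with the same
half-angles as the conversion formulas (they assume it), over a flat
floor at 3000 mm.  Upright actors are a spherical head cap (250 mm
diameter), a shoulder slab (450 mm breadth, top at height − 250 mm) and
a torso disk; falling is a 0.4 s morph of the body slab from standing
top height to a 350 mm prone slab — kept below the 400 mm rule so a
settled fall is detectable by construction, and configurable.  Sensor
imperfections are emulated by ±5 mm uniform integer depth noise and a
0.5 % dropout rate (exact count, drawn without replacement from a seeded
generator); both are off in the worked-example fixtures where exact cell
patterns matter.  Rendering is deterministic per (scene, seed), and the
per-frame ground truth records centres, body-top heights, prone flags
and pixel masks.

What the simulator does *not* emulate: articulated limbs, IR speckle and
material-dependent dropout structure, motion blur, lens distortion, and
soft deformations of a falling body.  Passing the end-to-end suites
therefore demonstrates the pipeline's logic — segmentation, recognition,
tracking, fusion handling, the fall rule and the value of a reference
frame — under the stated geometry, not sensor-grade performance on real
recordings.

The five canonical scenarios fix the study conditions: `simple_fall`
(6 s: enter, walk, fall at 3.0–4.3 s, rise, leave; one distant desk),
`complex_fall` (7 s: brush a chair, fall against a desk at 3.2–5.2 s —
the scene where a flat-floor reference merges person and desk and the
fall is missed, while the true reference keeps them separable),
`fusion_walk` (5 s: two subjects of 1700 and 1680 mm meet in shoulder
contact among three furniture pieces), `outstretched_arms` (the U-shaped
silhouette) and `table1_seven_blobs` (seven disjoint slabs laid out so
the labeler discovers them in a fixed row-major order).  Problem sizes —
150–210 frames per scenario, 500 oracle grids up to 64×64 — are chosen
so each suite finishes in well under the durations stated in the tests
while still exercising every code path.

## Numerical and boundary conventions

* Coordinates are 1-based `(x = column, y = row)` everywhere, matching R
  and the worked examples; depths are integer millimetres; nulls are 0.
* Null filling scans left-to-right: interior runs take the nearest valid
  value to their left, a leading run takes the first valid value to its
  right, an entirely null row becomes floor.  The operation is total and
  idempotent.
* Floor clamping uses `max_height − depth ≤ floor_band`; foreground uses
  a strict `> th_person`; the fall rule is strictly `< 400` (400 mm
  itself does not alarm); the head-ground step uses `≥ depth/2`.
* Sobel gradients use edge replication at the borders, so border pixels
  have well-defined magnitudes.
* The edge carve is applied where the gradient is **at least**
  `th_sobel`, on the sliced foreground frame — carving below the
  threshold would erase object interiors, and carving the un-sliced
  frame would lose the guarantee that person/furniture boundaries exceed
  a fixed threshold.
* Ties: the central super-pixel breaks centroid ties to the smallest
  row, then column; `cp` is the centre pixel of the central
  super-pixel's 8×6 block; the peak point snaps to the nearest blob
  pixel if rounding leaves a concave footprint.
* The reference frame is the pixel-wise median of the warm-up frames and
  stays fixed for the whole run; no background adaptation is attempted.

## Known limitations

* A person who enters already prone is never promoted (the head checks
  need an upright silhouette), so a fall that happened outside the view
  cannot be reported — inherent to the method, not a defect.
* Very slow sagging onto furniture at furniture height can keep a track
  above the threshold; the fall rule is purely geometric.
* The containment tracker assumes per-frame motion small enough that the
  stored central super-pixel stays inside the subject's next blob
  (comfortably true at 30 fps walking speeds).
* Coverage shrinks with subject height: a 1700 mm head is only visible
  within roughly ±0.8 m of the optical axis at a 3 m mount — scenario
  trajectories respect this.
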
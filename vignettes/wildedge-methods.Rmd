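---
title: "Methods: tiling, evaluation and edge notification for drone wildlife surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiling, evaluation and edge notification for drone wildlife surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wildedge)
```

## The problem

Aerial surveys for megafauna (rhino, giraffe, ostrich, springbok — plus
humans, for the anti-poaching context) capture very high resolution frames
— up to 6,000 × 4,000 px — in which the animals of interest are small,
typically boxed under 200 px on a side. Feeding such frames to a
fixed-input detector forces a downscale that destroys exactly the pixels
that distinguish an animal from scrub. In the field, a second constraint
bites: connectivity is too poor to stream video, so detections must travel
as small, self-contained notifications over a lossy link.

`wildedge` implements the data-preparation, evaluation and notification
machinery around a pluggable detector: tiling with label retention,
leakage-free dataset splits, label-aware augmentation, AP/mAP/confusion
evaluation, a throttled at-least-once notification channel with a GeoJSON
sink, and a seeded synthetic scene generator that stands in for field
imagery so every stage is testable end to end. Detector training itself is
out of scope; the package treats a detector as any function from a frame
to a table of `(class, box, confidence)` rows.

## Coordinate conventions

Pixels are 0-based. Pixel boxes are **half-open** rectangles
`[x0, x1) × [y0, y1)`: the box covers pixel columns `x0 .. x1-1`. This
makes tiling arithmetic exact — areas, intersections and retention ratios
computed from corner coordinates equal literal pixel counts, which is what
the test suite's brute-force oracles exploit. On disk, labels use the YOLO
normalized center format (`class cx cy w h`), written with 6-decimal fixed
formatting so files diff reproducibly; the write→read round trip is
identity to within 1e-6 per field.

Normalized-to-pixel conversion rounds each corner symmetrically
(`x0 = round(W(cx − w/2))`, `x1 = round(W(cx + w/2))`); a conversion whose
rounded corners coincide is rejected rather than silently producing a
zero-area box. Reading a label that extends outside the image is an error
by default — label spill is exactly what the manual QC loop exists to
catch — with an explicit `clamp = TRUE` escape hatch.

## Tiling

A frame whose width *or* height exceeds `tiling_threshold` (default
1,280 px; a 1,280 px frame itself is *not* tiled) is cut into
`tile_size × tile_size` windows (default 1,280) whose interior neighbors
share `overlap` pixels (default 320, one quarter tile). Along each axis
the origins are `0, s, 2s, …` with stride `s = tile_size − overlap`, while
a further full tile still fits strictly inside the image, plus one final
origin at `extent − tile_size`. The final pair of tiles may therefore
overlap by more than 320 px; the alternative — padding the image out to a
multiple of the stride — would manufacture black borders that no real
frame has. A dimension smaller than the tile simply spans its full extent.

The quarter-tile overlap carries a guarantee that the suite tests as a
property: any box with both sides ≤ `overlap` lies wholly inside at least
one tile, because consecutive tile windows advance by `s` while covering
`tile_size = s + overlap` pixels. With ~99% of survey boxes under 200 px,
nearly every object survives tiling uncut.

Objects cut by a tile edge follow the **retention rule**: a ground-truth
box is kept on a tile only when *strictly more than* `min_retention`
(default 0.5) of its area lies on that tile — a box exactly bisected is
kept on neither side of that edge (though usually on a neighboring tile in
the overlap). Kept boxes are clipped to the tile window, never
extrapolated: a tile's labels must lie inside the tile raster. Retention
is measured as the ratio of axis-aligned intersection area to box area;
no additional minimum-absolute-size filter is applied after clipping, so a
box barely above half-retention survives at its clipped size.
`map_to_parent()` inverts the transform (clipped boxes map back to the
intersection of the original with the tile window), which is the hook a
later inference-time tiling layer would use; inference in `run_flight()`
deliberately runs on whole frames.

## Dataset construction

Consecutive frames of one video are near-duplicates, so a frame-level
random split would leak: the model sees frame *t* in training and is
scored on frame *t+1*. `split_by_source()` therefore assigns whole source
videos to one side. The target is an 80:20 frame split; the algorithm
shuffles sources under the seed and assigns them greedily to the training
side until the training frame count first reaches the target fraction.
With equal-length videos this is exact; with uneven videos it is as close
as whole-video assignment permits. A single-source dataset cannot be split
without leakage and is an error.

`background_check()` enforces the working guideline that at least 10% of
training frames should contain no objects (background frames suppress
false positives); the fraction is reported either way.

Of the augmentations, only the three that transform labels are implemented
here — mosaic (2×2 grid, labels scaled/offset per quadrant), mixup
(alpha-blend, union of hard label sets — YOLO files carry no label
weights) and flips (center reflection). Pixel-only transforms (blur, HSV,
noise) have no label contract to test and belong to the training
backend's configuration.

## The noisy-oracle detector

Real trained weights are a build artifact, not a library function, so the
package ships a detector that *emulates* one with controllable error
rates: per-object misses (Bernoulli `miss_rate`), corner jitter (Gaussian
`jitter_sd`, clamped to the frame, redrawn on collapse), uniform
confidence bands for true and false positives, and Poisson false
positives per frame. Its output is a deterministic function of
`(frame_id, config seed)`, which makes end-to-end flight simulations
exactly replayable. Because the programmed rates are known, evaluation can
be checked for *parameter recovery*: with `miss_rate = 0.2` and no other
noise, measured recall and AP must land in the 99% binomial confidence
interval around 0.8 — a calibration test of the whole
detect→match→score path, not of any single function. A second,
pixel-driven implementation (`color_match_detect()`) finds synthetic
objects by their class color signature, providing a label-independent
cross-check of the detector contract.

## Evaluation

IoU is intersection over union of half-open pixel rectangles. Matching is
greedy in descending confidence: each detection claims the unmatched
same-class ground-truth box of highest IoU at or above the threshold
(default 0.50); unclaimed detections are false positives, unclaimed ground
truth false negatives. Ties break by higher IoU, then lower ground-truth
index, so results are deterministic. Greedy matching equals the optimal
assignment whenever each detection has at most one above-threshold
candidate — the overwhelmingly common case at IoU 0.5 — and the suite
verifies agreement with an exhaustive-enumeration oracle on small
instances.

AP uses **all-point interpolation**: detections pooled over frames are
sorted by confidence, cumulative precision/recall computed, the precision
envelope (running maximum from the right) integrated over recall. This is
the continuous-interpolation convention of modern detection toolchains,
not the older 11-point average. AP is therefore invariant under any
strictly monotone rescoring of confidences, which the suite asserts. mAP
is the unweighted mean over classes with at least one ground-truth box;
zero-ground-truth classes are reported as `NA` and excluded.

The confusion matrix answers a different question — *what did each animal
get called?* — so it uses class-agnostic IoU pairing: a rhino predicted
as giraffe lands in the (rhino, giraffe) cell rather than being invisible
as one FP plus one FN. Unmatched ground truth goes to the background
column, unmatched detections to the background row. Detections below a
0.25 confidence floor (configurable) are ignored here, mirroring common
detector reporting defaults. Raw counts are emitted; row- or
column-normalization is a rendering option in `autoplot()`, since either
direction is defensible and they answer different questions.

## Edge notification

A frame is forwarded iff at least one detection has confidence *strictly
over* the send threshold (default 0.5); sub-threshold detections are
removed from the bundle. The boundary is strict — a detection at exactly
0.50 never transmits — and the suite pins this behavior. All surviving
detections of a frame travel in **one** bundle together with the frame id,
capture timestamp, the aircraft's GPS fix and a single annotated image
payload, so class, frame and location cannot be mismatched in transit.
The fix is the *drone's* position in WGS84 decimal degrees; no camera
model projects the animal to a ground coordinate.

The wire format is a versioned JSON envelope with the annotated frame as
a base64 PNG. PNG keeps the payload self-describing and losslessly
compressed; at the simulation's frame sizes it is far smaller than the raw
raster. Transport follows MQTT QoS-1 semantics: the publisher retries
until acknowledged, so duplicates are possible, and the subscriber
deduplicates by the deterministic `message_id` — under any scripted loss
pattern with eventual success, every bundle is stored exactly once. Tests
run against an in-process channel simulator with scriptable drops,
duplicates and a bounded retry backlog; a real broker is an integration
target, not a test dependency.

At 30 fps a single animal in view would generate hundreds of
notifications, so `throttle_frames()` rate-limits: one notification per
`frame_stride` detection-positive frames (the counter advances only on
positive frames and is not reset by gaps), plus an optional per-class
cooldown in seconds. Stride 10 at 2 fps means at most one notification
per ~5 s of continuously visible wildlife. The stride is a policy knob:
the right value depends on flight speed, altitude and the camera's ground
footprint, and the policy object is the slot where a footprint-based
formula would plug in.

Stored bundles export to a GeoJSON FeatureCollection — one Point per
bundle at `(lon, lat)`, with classes, maximum confidence and an image
reference as properties — consumable by any web map.

## The synthetic scene generator

The generator reproduces the *statistics* a survey dataset imposes on this
machinery, not its appearance:

* **frame formats** drawn from the mixture observed across survey
  platforms (4,000 × 3,000 and 6,000 × 4,000 stills, 3,840 × 2,160 and
  1,280 × 720 / 1,920 × 1,080 video), weighted toward the still-camera
  formats that dominate collection;
* **box sizes** log-normal with `meanlog = log 60` and `sdlog` solved so
  the 99th percentile sits at 200 px — matching the observation that ~99%
  of real boxes are under 200 px — capped at half the frame;
* **background share** 10% by default, the training guideline's floor;
* **objects** as class-colored ellipses inscribed exactly in their
  ground-truth boxes, giving a pixel-level oracle for box tightness and
  enabling the color-matching detector;
* **flights** as ordered frames sharing a `source_id`, objects persisting
  with a small random walk (the leakage hazard made concrete), a
  lawnmower GPS track at constant altitude, and per-frame background
  swaps (empty ground passing beneath the camera).

What it does *not* emulate: photorealistic texture, occlusion, shadows,
motion blur, altitude-dependent scale drift, class imbalance, or
inter-object contact. Green tests therefore certify the geometry,
bookkeeping and transport of the pipeline under realistic *structure*;
they say nothing about any detector's accuracy on real imagery, which is
exactly the part the pluggable-detector boundary leaves to trained
weights. Because manifests, labels and tracks are pixel-free, the
generator renders rasters only on request (`render = FALSE` otherwise);
a 6,000 × 4,000 raster is ~576 MB as an R double array, and none of the
split/quantile/background statistics need it.

## Problem sizes and numerical choices

The test suite chooses sizes that keep the brute-force oracles exhaustive:
per-pixel tiling checks run on a proportionally scaled spec (96 px tiles,
24 px overlap) over ~500 random instances plus the default-spec grid
layouts on 3,840 × 2,160 (8 tiles) and 6,000 × 4,000 (24 tiles); the
small-box guarantee is exercised 1,000 times at full scale (label-only);
IoU is checked against pixel counting on 1,000 random pairs; parameter
recovery uses 600 objects; flight simulations run 200 frames at 320 × 180
— the notification path is raster-size-agnostic, so small frames test it
without ballast. Seeds are fixed in every stochastic test, and check
tolerances come from exact arithmetic or 99% binomial intervals, never
from observed spread.

Degenerate inputs are rejected loudly: zero-area boxes, invalid
latitudes, empty bundles, single-source splits, alpha outside `[0, 1]`.
Where a convention was genuinely open — rounding direction, edge-tile
policy, confusion-matrix normalization, mosaic quadrant order, tie-breaks
— the choice is documented at the function and, where observable, pinned
by a test.

## Known limitations

* No inference-time tiling with cross-tile NMS; `map_to_parent()` is the
  extension point.
* The external-model adapter is a file-format contract
  (`read_predictions()`), not a live model wrapper.
* Video I/O supports multi-frame TIFF and PNG-sequence containers; camera
  codecs are expected to be transcoded upstream.
* GPS semantics are bare WGS84 decimal degrees; fix age, datum shifts and
  dilution of precision are not modeled.
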
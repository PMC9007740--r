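---
title: "Methods: the multipose computational core"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the multipose computational core}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multipose)
```

## Scope and design

`multipose` implements the non-neural computational core of a multi-animal
pose-tracking pipeline. A trained network normally sits between two halves of
such a system: labeled poses are *encoded* into gridded target tensors the
network learns to predict, and predicted tensors are *decoded* back into
per-animal poses, linked over time, and scored. Everything on either side of
the network is deterministic, testable signal processing — and that is what
this package provides, with a synthetic scene generator standing in for the
camera and the network so the full loop can be exercised at desk scale.

The package deliberately contains no learning code. Its encoded tensors are
exactly what a training pipeline needs as regression targets, and its
decoders accept any tensors of the right shape, whether produced by
`encode_confidence_maps()` (the "oracle network") or by a real model in
another framework via the HDF5 tensor interchange (`save_tensors()` /
`load_tensors()`).

## Data model

A **skeleton** is a directed tree (or forest) over named body parts;
direction matters because edges drive bottom-up grouping from stable parts
(thorax, spine) outward to extremities. `validate_skeleton()` returns all
invariant violations (index range, self-edges, duplicates, in-degree,
cycles) as descriptions rather than raising, so interactive tools can report
them together. An **instance** is one animal's `n_nodes x 2` coordinate
matrix with a visibility flag per node; invisible nodes are `NA` with
`visible = FALSE`, and every metric masks on the flags so the `NA` never
propagates. Frames collect instances; a **dataset** adds the skeleton, a
track registry, optional class names and the image size, and round-trips
losslessly through a single portable HDF5 container (`save_labels()` /
`load_labels()`). Coordinates are (x, y), 0-based, full-image pixels, with
pixel centers at integer coordinates; node indices are 1-based in the R API
and stored 0-based in the container for cross-language portability.

Splitting for training follows the workflow defaults: 0.9/0.1
train/validation in routine use, 0.8/0.1/0.1 when a held-out test set is
needed. `make_splits()` uses largest-remainder rounding so the subsets are
always disjoint and exhaustive, and is deterministic given its seed.

## Target encoding

**Confidence maps.** The map for part $i$ at grid pixel $x_p$ is the
unnormalized Gaussian
$C_i(x_p) = \exp\!\left(-\lVert x_i - x_p\rVert^2 / 2\sigma^2\right)\delta_i$
with $\delta_i$ the visibility flag. The grid is the image subsampled by the
output stride $s_o \in \{1, 2, 4, 8\}$; grid pixel $p$ sits at image
coordinate $p \cdot s_o$ (no half-pixel offset, so a stride-1 grid *is* the
image grid), and $\sigma = \sigma_\mathrm{base} \cdot s_o$ keeps the spread
fixed relative to image resolution. Maps from several animals combine by the
per-pixel **maximum**, which keeps nearby peaks separable. Each Gaussian is
evaluated only within $\lceil 8\sigma \rceil$ px of its center; the omitted
tail values are below $1.6 \times 10^{-14}$, far beneath every tolerance
used anywhere in the package, and the truncation makes encoding linear in
instance count rather than in grid area.

**Part affinity fields.** For each skeleton edge, the field at a pixel is
the source-to-destination unit vector weighted by
$\exp(-M^2/2\sigma_\mathrm{PAF}^2)$, where $M$ is the distance from the
pixel to its projection onto the edge segment, clamped to the segment
(projection ratio in $[0, 1]$). The exponent uses $M^2$: the printed form of
the weighting is ambiguous between $M$ and $M^2$, and only the squared form
is dimensionally a Gaussian, so the squared form is used and noted here
rather than silently assumed. Fields from several animals combine by
**summation**. $\sigma_\mathrm{PAF}$ defaults to 5 px (exposed in the
config); Gaussian weighting replaces the hard distance threshold of the
original affinity-field formulation, trading a small amount of sharpness for
smoother fields when animals interact closely. A zero-length edge (coincident
endpoints) has no defined direction; its field is left zero and a message is
emitted.

**Class maps.** For appearance-based identification, each animal's visible
parts are dilated into binary disks of fixed radius, collapsed into one
channel per identity class. Where disks of *different* classes overlap, the
contested pixels are zeroed in every channel. The alternative (splitting or
letting the later writer win) would bake contradictory supervision into the
targets; zeroing makes the ambiguous region carry no signal at all, which is
the only choice that cannot mislead the downstream assignment. This is a
package decision on a point the method description leaves open.

## Decoding

**Peak finding.** Single-animal (or top-down crop) maps are decoded by the
per-channel global argmax; multi-animal maps by local peaks, defined as
pixels strictly greater than all eight neighbors. The implementation uses
grayscale dilation with the center pixel excluded and compares the map
against the dilated map, with implicit $-\infty$ padding at the borders;
a property test holds it equal to the literal pixel-by-pixel definition on
thousands of random maps. Both detectors drop peaks below a confidence
threshold of 0.2 — low enough to keep uncertain detections, high enough to
reject parts predicted as invisible. Two policies are package decisions
where the method description is silent: plateaus yield no peak (strict
inequality), and ties in the global argmax break toward the lowest (row,
column) in raster order, making decoding fully deterministic.

**Integral subpixel refinement.** Grid-aligned peaks are refined by the
confidence-weighted mean offset of the surrounding 5×5 patch (clipped at map
borders; an all-zero patch leaves the peak unmoved), and the refined grid
coordinate is scaled by $s_o$ back to image pixels. The weights are the raw
confidence values — no re-normalization beyond division by the patch sum.

One numerical property of this estimator deserves honesty: because the 5×5
patch *truncates* the Gaussian, the weighted centroid is biased toward the
patch center, and the bias grows with $\sigma_\mathrm{base}$ (the spread in
grid units). At the encoding default $\sigma_\mathrm{base} = 1$ the
worst-case per-axis bias is about 0.05 grid units, so refined decoding is
accurate to well under 0.25 px for strides up to 4 — the regime the
acceptance suite certifies on one hundred seeded scenes. At
$\sigma_\mathrm{base} = 2$ the worst-case bias is ~0.24 grid units and at
3 about 0.4; a test characterizes this growth rather than pretending the
estimator is unbiased. Users who decode with broad maps should prefer
stride 1, where the bias stays below a quarter pixel through
$\sigma_\mathrm{base} = 2$.

## Bottom-up grouping

Candidate connections between source and destination peaks of each edge are
scored by a line integral: the mean, over ten evenly spaced points between
the two peaks (endpoints included), of the dot product between the field
sampled at the point (nearest grid pixel; bilinear sampling available) and
the candidate's unit direction. The printed form of this score omits the
averaging its accompanying text implies; the mean is used here so scores
live in $[-1, 1]$ and the acceptance threshold (`min_connection_score`,
default 0.05) is independent of the sample count. A dense 1000-point
integration oracle agrees with the 10-point score to within 0.05 in tests.

Per edge, sources are assigned to destinations by Hungarian matching
(an in-package $O(n^3)$ shortest-augmenting-path solver, verified against
exhaustive permutation search up to 5×5). Accepted connections are then
assembled greedily in skeleton topological order: a connection extends the
partial instance holding its source peak, merges two node-disjoint partial
instances, or seeds a new instance; when a merge would fill one node twice,
the higher-scoring connection wins and the other is discarded. Unconnected
peaks become single-node instances only when `allow_singletons` is set, and
the output can be capped at `max_instances` by descending summed connection
score. The assembly algorithm's published details live in supplementary
material not reproduced here, so this module defines a concrete
deterministic variant and certifies it by oracle equivalence — on clean
encoded scenes its total score equals the exhaustive per-edge-permutation
optimum, and the recovered grouping equals the ground truth.

## Top-down decoding and identity

The top-down path centers a fixed-size square crop on each animal's anchor —
a designated stable part, or the bounding-box centroid of the remaining
visible parts when the anchor is occluded. The crop size is computed from
the labels: the smallest even multiple of 32 covering the largest instance
bounding box plus margins. Crops record their full-precision anchor and
integer offset, so poses decoded inside a crop (global peak + refinement)
map exactly back to full-frame coordinates, including for crops that hang
off the frame edge (zero-padded).

Identity assignment is cast as optimal matching. From class maps, each
instance scores against each class as the mean map value sampled at its
visible peaks; from a classifier, the per-crop probability rows are used
directly. Either way a single Hungarian assignment maximizes the total and
enforces mutually exclusive identities; surplus instances (more detections
than classes) are left unassigned, never forced.

## Flow-shift tracking

Tracking associates instances across frames with a window of recent tracked
frames. Each active track carries its latest detection forward,
advected frame-to-frame by sparse pyramidal Lucas–Kanade optical flow
estimated at the pose's points (pure R; a 15 px window over a 3-level
pyramid, iterated to convergence — a deliberately simple, training-free
flow). Points whose local structure tensor is degenerate (featureless
patches) are flagged and keep their coordinates. The matching cost between
a shifted candidate and a new detection is the mean Euclidean distance over
jointly visible nodes ($+\infty$ with no shared nodes); assignment is
minimum-cost one-to-one, pairs above `cost_threshold` are rejected, and
unmatched detections spawn new tracks. The default threshold is half the
median instance bounding-box diagonal, measured on the first frame.

Window semantics are package decisions on points the method description
defers to its supplement: the candidate set holds the most recent occurrence
of each track; unmatched tracks stay dormant — still advected, still
candidates — until they have gone `window_size` frames without a match;
tracks are never merged and ids never reused. Determinism is tested, and on
generated sessions with per-frame displacement below half the cost threshold
the tracker is certified switch-free over 500-frame, 2- and 4-animal
sessions against generator ground truth.

## Evaluation

**OKS.** Pose similarity is
$\mathrm{OKS} = \sum_i \exp\!\left(-\lVert X_i-\hat X_i\rVert^2 / 2\alpha\sigma_i^2\right)\delta_i \,/\, \sum_i \delta_i$
with $\delta_i$ the ground-truth visibility, $\alpha$ the area of the ground
truth's visible bounding box, and $\sigma_i = 0.025$ for every node (the
uncertainty of the least ambiguous human keypoint, making the score a lower
bound). A node the prediction misses contributes zero, so recovering $k$ of
$n$ visible nodes exactly scores $k/n$ — the two worked examples (4/5 = 0.8
and 10/11 ≈ 0.91) are the package's exact-value acceptance targets. A
degenerate (zero-area) bounding box is floored at 1 px² so single-point
instances still score.

**mAP/mAR.** Instances are matched greedily by descending OKS within each
frame. For each OKS threshold in $\{0.50, 0.55, \ldots, 0.95\}$,
predictions sort by OKS, cumulative TP/FP counts give precision and recall
(matched pairs below the threshold count as both FP and FN; matching is not
recomputed per threshold — an explicit decision where the source is
ambiguous), and average precision is the mean of interpolated precision at
101 evenly spaced recall points, taking the best precision among samples at
recall at or beyond each point and zero where unreachable. That
interpolation direction is the standard benchmark convention; it is also the
only reading under which a set of all-exact predictions attains mAP = 1,
which the contract requires. An independently coded naive oracle pins the
implementation in tests.

**Identity switches.** A switch is counted when a ground-truth identity's
OKS-matched predicted track differs from its most recent previous
assignment — the standard multi-object-tracking definition — and reported
both as a count and per 100,000 frames. The established Python MOT-metrics
package is not available in this environment, so the cross-check is a
hand-traced oracle plus an independent re-implementation over explicit
assignment sequences.

## Closed-loop approach trigger

The social features for a female–male dyad are the male-head to
female-abdomen-tip distance (mm), and the angular location of each animal's
thorax relative to the other's heading, wrapped to $(-180°, 180°]$. Heading
is defined as the thorax-to-head vector — the description does not pin this
down, and a fitted body axis would serve equally; thorax→head is the
simplest choice expressible in the labeled skeleton. Angles are signed
counterclockwise-positive in y-down image coordinates. The trigger is the
strict conjunction (distance < 2 mm) ∧ (|female angle| < 25°) ∧
(|male angle| > 145°), exactly as printed; any unavailable feature
(occluded node, degenerate geometry) yields `FALSE`. Monotonicity and
rigid-transform invariance are property-tested.

## Receptive field

For a convolutional stack, `compute_receptive_field()` evaluates
$\mathrm{RF} = 1 + \sum_i (K_i - 1)\prod_{j=1}^{i} S_j$ exactly as printed,
with the stride product including layer $i$'s own stride. The conventional
formula bounds the product at $j = i - 1$; both are exposed via the
`convention` argument and agree whenever all strides are 1. Neither reading
is asserted as the source's intent — randomized stacks are checked
term-by-term against direct evaluation for both.

## The synthetic world

`generate_scene()` and `generate_session()` emulate the regimes the
pipeline targets: 1–8 animals with body extents of tens of pixels, centroids
rejection-sampled (10,000-attempt cap) to respect a minimum separation,
poses drawn along the skeleton with segment lengths of 0.15–0.5 body scales,
optional per-node occlusion, and — for sessions — constant-velocity rigid
motion with Gaussian velocity jitter capped at `max_step` and reflection at
borders. Rendered frames draw one Gaussian blob per node with varying
amplitudes, enough texture for Lucas–Kanade flow. Everything is
deterministic given the seed.

What the generator does *not* emulate bounds what a green test establishes:
no photometric noise, motion blur, occlusion by overlap (occlusion is a
visibility flag, not an appearance change), non-rigid articulation within a
session, or animal entries/exits. Green pipeline tests therefore certify the
*computational* correctness of encoding, decoding, grouping, tracking and
scoring — not robustness to imaging conditions, which lives in the network
being emulated. Test scene sizes (128–256 px frames) are scaled down from
the 1024 px frames typical of real recordings purely for runtime; the
coordinate conventions are resolution-independent.

## Known limitations

- The integral-refinement bias analysis above means sub-quarter-pixel
  decoding at stride 4 requires narrow maps ($\sigma_\mathrm{base}$ ≈ 1);
  broad maps at coarse strides trade accuracy for smoothness.
- The tracker has no re-identification: a track lost for more than
  `window_size` frames is never resumed.
- Greedy assembly is certified optimal on clean, well-separated scenes;
  with heavily overlapping animals the per-edge greedy order can in
  principle diverge from the global optimum, as with any greedy parser.
- The Lucas–Kanade implementation is pure R and sized for desk-scale
  fixtures, not real-time video.
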
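---
title: "Differential flock detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential flock detection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flockwatch)
```

## The problem

Bird flocks — above all European starlings — can destroy a fruit harvest
in the ripening weeks. Scaring devices that fire continuously lose their
effect because the birds habituate, so the system modeled here fires only
on a *flock*: five or more birds flying together. The software chain is
(1) find anything that moves, (2) decide what it is, (3) trigger the
actuator only for a sufficiently confident flock, and the package adds
(4) the machinery to score such a detector against annotated ground truth
and (5) a synthetic scene generator so the chain can be exercised without
field recordings.

## The motion detector

For frames $I_t$ (8-bit grayscale; color input is collapsed by luma
weights before differencing, since motion evidence is intensity change),
the detector computes

$$D_t = |I_t - I_{t-1}|,$$

subtracts the accumulated background, thresholds, and extracts connected
components. The absolute value is a deliberate choice: the sign of an
intensity change says nothing about whether something moved.

**Accumulated background.** Vegetation quivers perpetually, so a naive
differencer fires on leaves forever. The accumulated background is an
exponential moving average of past differential images,

$$B_t = (1 - \alpha) B_{t-1} + \alpha D_t, \qquad B_0 = 0,$$

and each new differential is filtered as $\max(D_t - B_{t-1}, 0)$ before
thresholding (clamped at zero — negative evidence is meaningless for a
binary detector). "Accumulated" admits several readings (unbounded sum,
sliding window, EMA); the EMA was chosen because it is the standard
recursive form, needs no frame history, and decays stale motion
geometrically. A patch flickering by ±a contributes a differential of
$2a$ every frame; the filtered residual after $k$ frames is
$2a(1-\alpha)^k$, so with the defaults ($\alpha = 0.05$, threshold 25 of
255) a ±15 flicker is silenced within a ten-frame warm-up while a bird
passing once is untouched. The accumulator absorbs $D_t$ *after* frame
$t$ is scored, i.e. filtering always uses the background as of the
previous frame.

**Defaults.** Threshold 25/255 and minimum component area 4 px are
configurable; they suit the synthetic scenes' contrast (object intensity
≥ 90 levels above background, sensor noise σ = 2, whose frame-difference
σ ≈ 2.8 never nears 25). Frame 0 emits no detections — there is no
previous image.

**Components, not contours.** Object extraction labels 8-connected
components (diagonal contact joins) of at least `min_area` pixels and
reports tight bounding boxes; for solid components this is equivalent to
tracing binary contours, and 8-connectivity tolerates 1-px diagonal gaps
in small distant birds. Labeling is a breadth-first flood fill written
in-package because the available image-analysis labelers here are
4-connected. Boxes are 0-based, half-open, and sorted by $(y_0, x_0)$ so
logs are reproducible.

**A property worth knowing.** Pure two-frame differencing sees both the
old and the new footprint of a moving object. If the displacement is
below the blob size the footprints overlap and merge into one component;
at a displacement equal to the blob size they join edge-to-edge (one
component covering both); beyond that they split into a "ghost" at the
old position plus the object at the new one. The object-count
conservation test therefore plants displacements equal to the blob
diameter. Similarly, threshold monotonicity (more threshold, fewer boxes)
holds for uniform-contrast objects; a textured component can in principle
split into several boxes as the threshold rises.

## Classification and flock grouping

The deployed system used a cloud-trained convolutional network; training
it is out of scope and its imagery is not available. The package instead
fixes a *classifier contract* — `function(frame, boxes) -> detections
with confidences` — and ships a reference heuristic so the rest of the
chain is testable: area ≤ 2 px ⇒ bug (insects sit near the lens but
subtend almost nothing), area ≥ 100 px ⇒ helicopter, otherwise bird;
confidence grows with area (small distant objects are genuinely less
certain), capped below 1. The heuristic is a stand-in, not a model of the
network's accuracy; any adapter with the same signature plugs in.

A **flock** is ≥ 5 birds flying together. "Together" is operationalized
as single-linkage clustering of bird-box centers cut at a proximity
distance, by default 4× the median bird-box diagonal (an adaptive scale:
birds look closer together when they are smaller/farther). Each cluster
of ≥ 5 becomes one flock detection — box = cluster hull, confidence =
mean member confidence (the simplest aggregate consistent with the
members' scores); clusters of ≤ 4 pass through as birds. Grouping never
creates or destroys objects and is invariant to input order. Whether a
trained classifier should emit flock boxes directly or post-group bird
boxes is left open by design: the contract allows the former, and
`group_flocks()` covers the latter.

## Evaluation

A detection is valid when its IoU (Jaccard index) with a ground-truth box
is at least 0.5. Matching is one-to-one and greedy in descending
detection confidence, each detection taking the free annotation of
highest IoU (ties to the lower annotation index); with distinct
confidences the result is independent of input order. Labels are ignored
at match time: a cross-class match counts as a false positive for the
predicted class *and* a false negative for the true class, and feeds the
confusion matrix cell (truth, predicted). Detections matching nothing are
tallied per predicted class as *out-of-class* false positives. This
bookkeeping makes per-class FP totals reconcile exactly with the
confusion matrix.

Per class, with TN fixed at 0 (object detection has no natural
true-negative count):

$$\text{precision} = \frac{TP}{TP+FP},\quad
  \text{recall} = \frac{TP}{TP+FN},\quad
  F_1 = \frac{2TP}{2TP+FP+FN},\quad
  \text{error rate} = \frac{FP+FN}{FP+FN+TP+TN}.$$

Percentages are rounded half-up to one decimal (banker's rounding would
print 5.65 as 5.6). Each metric raises an error when its denominator is
zero rather than inventing a value; the batch evaluator reports `NA`
there.

`make_fixture_from_counts()` inverts the bookkeeping: given per-class
tallies and a confusion matrix it lays out disjoint unit boxes
(coincident where a match is wanted) whose evaluation reproduces the
tallies exactly. That turns a published results table into an executable
regression input. Applied to the reference per-class table (1008
ground-truth objects), the pipeline reproduces every published recall and
error-rate figure and the flock/helicopter precision and F1. The
published bird precision/F1 (83.4/83.4) and bug precision/F1 (65.8/66.7)
do **not** equal the formulas applied to that table's own counts (which
give 83.8/83.6 and 66.7/67.1) — the package implements the formulas and
flags, rather than reverse-engineers, those two cells.

## Trigger policy

An actuator event fires iff a flock-labeled detection has confidence
≥ 0.30 — inclusive, and flock-only: a bird at 0.99 never fires. Two
options generalize the deployed single-frame behavior: `confirm_frames`
requires the qualifying flock in that many consecutive frames (a flock is
normally captured in several images, so confirmation trades latency for
robustness), and `cooldown_frames` enforces a minimum gap between events
(actuator duty limits). Defaults (1, 0) reproduce the deployed behavior,
under which a persistent flock re-triggers every frame.

## Coverage planning

With a horizontal field of view $\phi$ and a 300 m detection radius,
$360/\phi$ cameras cover the full circle; the planner reports that figure
to one decimal (8.1 at 44.6°, 5.6 at 64.5°) plus the nearest-integer
recommendation. The fractional value is reported deliberately: at 44.6°,
eight cameras leave a 3.2° gap while nine close the circle with margin,
and the planner surfaces both rather than hiding the trade behind a
ceiling. Sector membership is inclusive at the angular edges and at
exactly the range limit.

## The synthetic scene generator

The generator emulates what the field cameras saw: small moving bird
blobs, coherent flocks, erratic near-lens insects, a large slow
helicopter, quivering foliage, and additive Gaussian sensor noise
(σ = 2 by default — real sensors are not noiseless, and a noise floor
keeps the thresholds honest). Blob sizes echo the classes' apparent
sizes at range: birds 2–6 px, bugs 1–2 px with large random-walk steps,
helicopters ≥ 15 px and slow. Flock members sit on a ring of radius
`spread` around the flock center with per-frame jitter; the ring keeps
members resolvable as distinct blobs, which is what makes "five or more
birds flying together" observable in the image at all — a fully merged
cloud of pixels is a single blob, not a countable flock. Ground truth per
frame is one tight box per object and one hull box per flock. All
randomness flows from the config seed, and the caller's RNG stream is
restored afterwards.

The **benign reference scene** used by the end-to-end self-consistency
check is 160×120 px, 20 frames, three six-member flocks crossing at
2 px/frame at high contrast (intensity 220 on background 60). On it, the
full chain — generate, detect motion, classify heuristically, group,
evaluate at IoU 0.5 — recovers flocks with ≥ 90% recall (the first frame
necessarily contributes three misses, since differencing needs two
frames) and the trigger policy fires. This is a self-consistency check of
the pipeline's plumbing, not a claim about field imagery: the generator
renders rigid square blobs under constant illumination, without wing
articulation, perspective, compression artifacts, clouds, or the
long-range blur that made small birds and insects hard in the field.

## Problem sizes

The test suite runs the detector-vs-oracle equivalence on 100 seeded
random 16×16 sequences, the quiver-suppression and static-scene checks on
24–32 px scenes, coverage sweeps at 1° steps, and the round trip on the
reference scene above; the whole suite completes in well under a minute,
and `scripts/acceptance.R` in a few seconds.
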
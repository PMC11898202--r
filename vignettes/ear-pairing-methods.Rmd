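---
title: "Methods: two-stage ear-root pairing and thermometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage ear-root pairing and thermometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earpair)
```

## The measurement problem

Group-housed pigs cluster at drinking troughs, and an overhead thermal
camera sees many ear roots at once. The ear root — the base of the pinna,
thinly haired and well perfused — is the hottest reliably visible surface
region and tracks core temperature well, but a *single* ear is a noisy
thermometer: pose, hair, and dirt attenuate it unpredictably. Using the
warmer of a pig's *two* ear roots suppresses that attenuation, which
requires knowing which detected left-ear box and which right-ear box belong
to the same pig. `earpair` implements that pairing step and everything
around it: oriented-box geometry, label and frame I/O, the radiometric
gray-to-temperature map, evaluation metrics, and a synthetic scene
generator that makes the whole pipeline testable without a camera or a
trained detector.

## Coordinate and angle conventions

Pixel coordinates are 0-based: `x` is the column index increasing
rightward, `y` the row index increasing downward, and pixel `(r, c)` has
its center at `(c + 0.5, r + 0.5)`. ROI membership everywhere (box
rasterization, reference-line bands, ellipse fills) is the
pixel-center-inside test, so areas and maxima are consistent across
modules.

Polar angles are measured counterclockwise from the +x axis in the **y-up**
sense, i.e. computed on `(dx, -dy)`. This is a genuine choice — with y-down
angles the left/right decision rule below assigns the anatomically wrong
ear. The choice is pinned by a calibration property that the test suite
asserts: on noiseless generated pigs of arbitrary heading, the polar
classification must name the anatomical left ear "left" (the generator
defines anatomical left as the ear on the pig's left when facing along its
heading).

Lines are stored in normalized implicit form `a x + b y + c = 0`
(`a² + b² = 1`), so vertical lines — which a point-slope form cannot
express — need no special casing. Two lines are treated as parallel when
the absolute sine of the angle between them falls below `1e-6`.

## Stage 1: rough pairing by minimum center distance

All detected ear-root boxes in a frame enter a greedy global-minimum
matching: among all unordered box pairs whose center distance lies in the
window `[d_min, d_max]` (default 80–160 px, the empirical range of same-pig
ear-center distances at the nominal camera geometry of a 384 × 288 frame),
the pair with the smallest distance is emitted and its boxes removed,
repeatedly, until no candidate remains. Ties break deterministically by box
order. Boxes left over are reported unpaired.

The rough stage is deliberately **class-agnostic**: it matches on geometry
alone and may pair two same-class boxes. That is not an oversight but the
property the second stage relies on. We verified (numerically, and by a
winding-sign argument: the polar decision reduces to the sign of
`cross(C_left − O, C_right − O)`) that a left box and a right box taken
from two different, naturally postured pigs almost always form a
geometrically coherent "phantom pig" whose polar reading *agrees* with the
detector labels — such a mispair is undetectable by any label-consistency
test. A same-class mispair, by contrast, is refuted by the labels outright.
A `class_constrained` option restricts rough candidates to one left with
one right for users who want the geometric stage to respect the detector.

## Stage 2: precise pairing in polar coordinates

A pig's two ear roots splay like the character "八": elongated boxes whose
long axes converge ahead of the head. For each rough pair the algorithm
reconstructs that convergence:

1. **Base points.** The nearest pair of vertices between the two boxes
   (exhaustive over the 16 combinations, ties by canonical vertex index).
2. **Outermost lines.** Within each box, the vertex nearest its base point
   *excluding the base point itself* and the vertex farthest from it span
   the box's outer long edge (ear boxes are much longer than wide, so the
   nearest other vertex lies across the short side and the farthest is the
   diagonal corner). Taking the nearest vertex *inclusively* would collapse
   the line onto the box diagonal; we verified that diagonals place the
   intersection on the wrong side of adversarial pairs and make every
   mispair look consistent, so the outer edge it is.
3. **Head origin.** The intersection `O` of the two outermost lines.
   Parallel lines mean no origin; the pair is kept with its detector labels
   but flagged (`stage = "fallback"`), or dropped under
   `parallel_fallback = "drop"` — silently discarding data would bias the
   temperature report toward well-posed pigs.
4. **Decision rule.** With `θ1`, `θ2` the polar angles of the two box
   centers about `O`, form `θ = (θ1 − θ2) mod 360`. If `θ < 180` the
   *second* box is the left ear; if `θ > 180` the *first* is. Read
   circularly like this, the rule is provably invariant to the order of the
   two boxes (`θ ↦ 360 − θ` swaps the branch and the selection), and for
   the worked pair with center angles 91° and 27° it yields `θ = 64°` with
   the 27° box as the left ear. `θ` exactly 0 or 180 is geometrically
   ambiguous; such pairs are kept but flagged, never silently classified.

A pair whose polar assignment matches the detector labels is
**confirmed**. A disagreeing pair — including any same-class rough pair —
is **dissolved**: its boxes join the rough-stage unpaired boxes in a pool
that is re-paired by the same greedy minimum-distance rule, one pool-left
with one pool-right, with two refinements:

* **Dissolved combinations are excluded.** A dissolved pairing won the
  distance competition once; re-admitting it would deterministically
  re-form it and the repair could never converge to anything else.
* **Pool classes are hybrid.** Boxes from a dissolved one-left-one-right
  pair carry their polar-derived classes (the polar reading is the best
  available evidence that the detector ordering was wrong); boxes from
  same-class mispairs keep their detector classes, because the polar
  classes of a refuted phantom carry no information and would block the
  correct same-pig re-pair; unpaired boxes never had polar geometry and
  keep detector classes.

Re-formed pairs are validated once more; surviving conflicts are kept as
`fallback` with `consistent = FALSE`. Exactly one repair round runs: it
reproduces the head-collision correction the algorithm exists for,
guarantees termination, and every input box provably ends in exactly one
final pair or the unpaired list (asserted as a conservation property on
every test scene).

## Thermometry

8-bit frames carry no radiometric scale, so each frame travels with its
minimum and maximum temperature (JSON sidecar) and gray level `P` maps to

$$T = \frac{T_{max} - T_{min}}{255}\,P + T_{min},$$

exact at both endpoints and strictly increasing. A pig's record is the
maximum temperature over each ear box (`t_left`, `t_right`) and their
maximum `t_pig`; one empty ROI degrades the record to a flagged single-ear
measurement rather than failing. Reference values for agreement analysis
come from a rectangular band of configurable width (default 5 px, the
modal width of the bright ear-root line) around a user-supplied segment —
the band endpoints are an input because their placement is a manual step
in practice. Temperatures are displayed at 0.1 °C; full precision is kept
internally.

## Evaluation

Detection quality uses rotated IoU (exact Sutherland–Hodgman polygon
clipping, checked against a dense rasterization oracle), greedy
confidence-ranked matching at a default IoU threshold of 0.5, and
all-point-interpolated average precision; mAP is the unweighted class
mean. With no predictions at all, precision is reported as 1 with a
degeneracy flag; recall with no positives is undefined and excluded. True
negatives are not applicable to detection and reported as such. Pairing
accuracy is `correct / total`, with the caller choosing the denominator —
published pairing tables mix "pairs evaluated" and "pairs including
exclusions" denominators, so both are expressible and each result carries
its own. Agreement between predicted and reference temperatures uses
Pearson correlation and a measurement-system bias analysis: per-sample
bias, its mean, n−1 standard deviation, the t-based 95 % confidence
interval, and the verdict "acceptable iff 0 lies inside the interval"
(sd = 0 is handled closed-form rather than through the t machinery).

## The synthetic scene generator

`generate_scene()` is the package's study-condition fixture: a pure
function of `(config, seed)` producing a frame plus complete ground truth
(boxes, true pairings, planted ear temperatures, reference lines).

Geometry defaults are the conditions the pipeline assumes: 384 × 288
frames; same-pig ear-center distance uniform on 80–160 px; splay
half-angle 25–40°; ear boxes 30–50 × 6–10 px whose long axes converge at
the head point ahead of the ears. Temperature levels are plausible barn
values chosen once (background ≈ 21 °C, body surface 30–34 °C, ear peak
35–39 °C) — they are design choices, not literature values, and fully
configurable. Each ear contains a hotter 5-px central line along its axis,
the hottest pixels in the frame; Gaussian sensor noise (default 0.5 gray
levels) is added before the field's extrema are recorded and the field is
quantized to 8 bits, so a planted peak is recoverable to within one
quantization step on noiseless scenes. An optional per-ear attenuation
(`ear_attenuation_sd`, degrees C, folded in as minus the absolute value of
a Gaussian) emulates pose/hair/dirt losses and is how the package
demonstrates the bilateral-max advantage: with asymmetric attenuation, the
two-ear maximum correlates with the planted truth at least as strongly as
either single ear.

Two adversarial modes exercise the failure scenarios that motivate the
precise stage. `touching_heads` builds a head-on collision: two pigs
facing each other, heads pushed past one another with a lateral offset
sampled so that the nearest in-window candidate is a *same-class*
cross-pig pair while both opposite-class cross distances fall below the
80 px window. Rough pairing then provably mispairs the two like ears and
strands the other two; the precise stage dissolves the mispair and
restores both same-pig pairs. `edge_clip` places a pig partially outside
the frame, the degenerate-ROI case. The generator emulates the
*statistical geometry* the algorithm consumes, not thermal imagery: no
occlusion, no motion blur, no emissivity or reflection artifacts, and
detector noise only via the configurable attenuation — passing tests show
the algorithmic machinery is correct under the stated geometry, not that a
particular detector performs well on real footage.

## Problem sizes and numerical choices

The test suite and acceptance checks run at sizes chosen to make the
properties sharp but cheap: 200 seeded single-pig scenes for the
perfect-rough-pairing property, 100 touching-heads scenes for the strict
rough-to-precise improvement, 200 scenes for the correlation ordering,
1,000 replicates (n = 100) for the 95 % CI coverage of the bias analysis,
and 100 random box pairs against the dense IoU oracle. Vertex ties break
by canonical index; degenerate quadrilaterals (duplicate or collinear
vertices, non-convex cycles) are rejected at construction; file round
trips are lossless to below 1e-6 px in both label dialects.

## Known limitations

Pairing is per-frame: no identity tracking across frames, and a pig whose
ears straddle frames is simply two frames' records. One repair round
means a pathological chain of interlocking mispairs may leave fallback
pairs; these are flagged, never silently resolved. The consistency test
cannot catch an opposite-class mispair that forms a coherent phantom pig —
the structural analogue of the residual errors any label-consistency
method must leave — and the generator's `touching_heads` band is built to
produce the detectable kind. Absolute radiometric accuracy is out of
scope: the package maps gray levels through the frame's recorded extrema
and does not model emissivity, atmosphere, or rectal-temperature
calibration.
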
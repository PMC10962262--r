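---
title: "Behavioral profiling of adult zebrafish in multi-tank optomotor assays"
author: "zebrafishOMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral profiling of adult zebrafish in multi-tank optomotor assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zebrafishOMR)
```

## The assay

Eight adult zebrafish swim in individual white tanks filmed from above at
one frame per second for three hours; the two stacked camera fields form a
640 × 960 px image holding all eight tanks. The trial divides into 18
ten-minute periods: a blank baseline hour (periods 1–6), an hour of moving
red lines (7–12), and a blank post hour (13–18). Line thickness and speed
step up every two periods — thin (1 mm, 7 mm apart, 10.8 cm/s), medium
(10 mm, 10 mm, 13.8 cm/s), thick (20 mm, 20 mm, 27.6 cm/s) — with odd
periods moving leftward and even periods rightward. `defaultSchedule()`
encodes this timeline; alternative orders (for example thick-to-thin) are
expressible through `scheduleFromConfig()` or a YAML file, and
`defaultSchedule(periodS =)` produces structurally identical compressed
trials used throughout this vignette's examples and the package tests.

Because the stimulus is pure red on a near-white tank bottom, the red
channel of each frame contains the fish at full contrast while the stripes
saturate into the background. Detection therefore runs entirely on the red
channel: per tank ROI the channel is thresholded (per-ROI Otsu by default,
a fixed level optionally), the dark foreground is decomposed into
8-connected components, components outside a plausible adult-fish area
(50–2000 px² by default at the 76 mm / 70 px scale) are discarded, and the
largest survivor becomes the single detection for that tank and frame,
carrying its centroid, tight bounding box and moment-based best-fit
ellipse.

## From detections to the 24-measure profile

Per-frame metrics follow fixed conventions, all stated here because each
one is a tie-break someone will eventually need:

* **Speed** is the centroid displacement between *temporally adjacent*
  detections, converted through the 76 mm / 70 px scale
  (`speed = |d|·mmPerPx/10/dt` cm/s). No interpolation is performed across
  missing frames — fabricating displacement over an occlusion biases speed
  upward — so a frame following a gap has undefined speed.
* **Moving** means strictly faster than 1 cm/s.
* **End zone** is the outer 20 % of tank length at either end
  (`cx < 0.2·W` or `cx ≥ 0.8·W`); **right half** is `cx > W/2`, with the
  exact midline counting as left.
* **Heading.** The moment ellipse fixes the body axis only modulo 180°.
  The head side is taken from where the centroid sits relative to the
  bounding-box center: the anterior body (head plus trunk) is heavier, so
  the centroid is displaced toward it along the axis. If the projection of
  that displacement on the axis falls below 0.2 px the previous heading is
  carried forward (and labelled `carried_forward` so analyses can filter).
* **Oriented right** requires a strictly positive x-component of the
  heading; exactly ±90° resolves to `FALSE`.
* **RFC / clockwise.** With y pointing down, the fish's right flank points
  along the heading rotated +90°; the flag is true when that vector has a
  positive dot product with the vector to the tank center. A fish that
  keeps its right flank toward the center circles clockwise when viewed
  from above.

Period summaries average these flags per fish per period, always over the
frames where the flag is *defined*: missing detections shrink the
denominator instead of dragging percentages toward zero, and an empty
denominator yields `NA` rather than a fabricated value.

The profile condenses the 18 summaries into 24 measures
(`profileMeasureNames()`), and the contrast measures need explicit sign
conventions, fixed as follows:

* startle (`M_St`, `E_St`) = period 6 − period 7 (pre − post), so a surge
  of activity at stimulus onset scores negative;
* acclimation (`M_Accl`, `E_Accl`) = mean(periods 1–3) − mean(periods 4–6);
* habituation (`M_Hab`, `E_Hab`, `OMRLHab`, `OMROHab`) = earlier − later
  same-direction period;
* optomotor indices (`OMRL`, `OMRO`) = (rightward-lines period) −
  (leftward-lines period) of the right-half / oriented-right percentage.

This is the unique simple difference scheme under which a fish that swims
*against* the lines (a negative optomotor response, the regime wild-type
adults show) produces negative `OMRL`/`OMRO`, a startle surge produces
negative `M_St`, and habituation of a negative OMR produces positive
`OMRLHab` — i.e. the sign structure of the published wild-type group
profile. Group summaries report the mean, the SEM with the sample (n−1)
standard deviation, and n; the n−1 convention reproduces the published
speed SEM to its printed precision (see `tests/testthat/test-acceptance.R`).

Spatial occupancy uses regular flat-top hexagons (`hexbin()`), anchored so
a hexagon center sits at the ROI origin, with a configurable circumradius
(default 10 px; the assay does not dictate a lattice). Assignment is
nearest-center via cube rounding with a nearest-neighbor refinement;
boundary ties go to the lexicographically smallest center so binning is
deterministic.

## The statistical layer

`friedmanTest()` uses the general tie-corrected rank-sum statistic
(reducing to the classical `12/(nk(k+1))·ΣR²−3n(k+1)` without ties) with a
χ² reference on k−1 df; `wilcoxonSignedRank()` drops zero differences,
mid-ranks ties, reports `W = min(W⁺, W⁻)` with an exact p for n ≤ 25
untied differences and a tie- and continuity-corrected normal
approximation otherwise; `rmAnova()` is the one-way within-subject
decomposition `SS_total = SS_subjects + SS_conditions + SS_error` with
`F = MS_cond/MS_err` on `(k−1, (k−1)(n−1))` df. No sphericity correction
is applied by default — the analysis this package implements did not use
one — but a Greenhouse–Geisser df adjustment is available as an option.
`bonferroniPairwise()` multiplies each of the `k(k−1)/2` raw p-values by
the number of pairs, capped at 1, wrapping either the signed-rank test or
a paired t. Two canonical condition groupings are provided: the 18
individual periods, and the four stimulus classes (blank first hour, lines
right-to-left, lines left-to-right, blank third hour).

The test suite checks each statistic against an independent route
(`stats::friedman.test`, `stats::wilcox.test`, `aov(… + Error(subj/cond))`,
sign-flip enumeration at tiny n) and calibrates the type-I error of the
omnibus tests on a 2,000-replicate exchangeable null with 16 subjects and
4 conditions.

Degenerate inputs are flagged rather than guessed at: an all-tied table
gives Friedman statistic 0 with p = 1, all-zero differences give W = 0
with p = 1 and a note, and a table with zero condition *and* error
variance yields an undefined F with a note.

## What the synthetic generator emulates

`simulateTrajectory()` is a discrete-time biased random walk in continuous
tank coordinates, one step per frame, fully deterministic given its seed.
Each frame the fish moves with probability `pMove`; a moving step draws a
speed from a zero-truncated normal and a direction from a drift vector
summing heading persistence, attraction to the nearest long wall
(thigmotaxis, `wallBias`), attraction to the nearest end (`endBias`) and
an optomotor term (`omrGain`, positive = with the lines) active only while
lines move, plus Gaussian angular noise. `startleGain` multiplies `pMove`
in the first period after each blank→lines transition and
`habituationRate` decays both the optomotor gain (per stimulus period) and
the startle surplus (per transition). Walls reflect the position inside a
16 px margin so a rendered body stays inside the ROI; the body heading
follows the *intended* swim direction, so a wall that stops the step does
not spin the fish — without this, orientation-based optomotor indices wash
out exactly where location-based ones saturate (at the tank ends).

Defaults describe the wild-type regime the assay observes: cruising speed
3 ± 1 cm/s, `pMove` 0.45 (≈ 42 % of frames moving), `endBias` 0.15
(≈ 65 % baseline end-zone occupancy), `omrGain` −0.6 (a robust negative
optomotor response), `startleGain` 2.0 (a ≈ 30-point activity surge at
onset) and `habituationRate` 0.7 (clearly positive habituation
contrasts).

The generator's bookkeeping computes the per-frame flags from the realized
positions and headings with *exactly* the kinematics definitions
(`expectedFlags()`), so on perfect detections (`trackDetections()`) the
kinematics module must reproduce them bit for bit — the package tests
assert that equality, which pins both implementations to the same
conventions.

`renderFrames()` rasterizes tracks into frames: near-white background
(245), pure-red stripes of the schedule's geometry translated at the
schedule's speed, and one dark egg-shaped body per tank whose half-width
grows toward the head (`headSkew`, default 0.3). The taper serves two
purposes: it displaces the bounding-box center from the centroid along the
heading (the detection stage's head cue, ≈ 1 px at the default geometry),
and the rasterizer re-centers the shape so the raster *centroid* lands on
the true position, which is what detection estimates. The background value
matters: the tank bottom's red channel must sit near the stripe's
saturated red, as it does under real illumination of a white tank —
otherwise the red-channel histogram becomes bimodal between background and
stripes and any variance-based threshold splits the wrong pair of modes.

What the generator deliberately does not emulate: biomechanical swimming
(tail-beat kinematics, burst-glide structure), illumination gradients and
shadows, water-surface refraction, occlusions, and any interaction between
tanks. Passing the end-to-end tests therefore demonstrates that the
pipeline's geometry, conventions and bookkeeping are exact and that
detection is robust to the stimulus overlay — not that detection would be
noise-free on real video.

## Numerical choices

* Coordinates are zero-based pixel indices, origin at the ROI top-left,
  x rightward, y downward; centroids are plain means of pixel indices.
  Consistency across modules matters here, not the half-pixel offset.
* The Otsu implementation maximizes between-class variance on a 256-bin
  histogram; when the maximum sits on a plateau (an empty gray-level gap
  between classes) the plateau midpoint is used, matching common
  image-analysis practice and keeping the cut away from either class.
* Ellipse axes are `4·√λ` of the second-central-moment eigenvalues (exact
  for a solid continuous ellipse), floored at the single-pixel spread
  1/12 so degenerate one-pixel particles keep `major ≥ minor > 0`; the
  orientation is the principal eigenvector's angle mod 180°.
* Ties resolve to the left/false branch everywhere (midline, exact ±90°
  heading, tangential RFC), and particle selection breaks area ties toward
  the smaller (y, x) centroid, so every stage is deterministic.
* Percentages are means of 0/1 flags scaled by 100; no rounding happens
  anywhere in the pipeline — rounding is the caller's presentation choice.

## Problem sizes in the tests

The suite exercises the full 3-h, 1 s-interval geometry (10,800 frames)
wherever imaging is not involved: trajectory simulation, kinematics,
profiles and the mirror anti-symmetry checks all run at trial scale.
Rendered-imaging tests use a 600-frame window spanning the blank→lines
transition for the detection-oracle comparison (8 tanks, rendered twice,
with and without stripes) and a compressed 18 × 60 s trial for the
end-to-end fidelity comparison; at 60 frames per period a single
frame-level disagreement moves a period percentage by 1.7 points, which
is why the fidelity bound of 2 points is a meaningful, not generous,
budget at this scale. The type-I calibration uses 2,000 replicates of a
16 × 4 exchangeable-normal null.

## Limitations

* One fish per tank is assumed structurally; two animals in one ROI are
  resolved to the larger particle, never tracked separately.
* The head/tail rule depends on the centroid–bounding-box offset; a
  symmetric silhouette (fish seen exactly head-on, curled bodies) falls
  back to carry-forward, and a long sequence of ambiguous frames carries a
  stale heading (the `heading_source` column records this).
* AVI containers are not read directly; movies enter as numbered PNG/TIFF
  frame sequences, in-memory arrays, or a frame-generating function.
* Speed is undefined after every detection gap by design; heavily occluded
  recordings lose `pct_move` denominators (the pipeline warns when a
  fish-period keeps less than half its nominal frames).
* The statistical layer tests the measures the pipeline computes; it does
  not model between-day or tank-position effects (no random-effect
  structure beyond the within-subject decomposition).
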
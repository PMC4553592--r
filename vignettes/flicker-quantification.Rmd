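---
title: "Quantifying flickering and shimmering from nest-surface video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying flickering and shimmering from nest-surface video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beeshimmer)
```

## The measurement problem

Giant Honey Bee (*Apis dorsata*) colonies coat their single open comb with
a living curtain of bees. Two motion behaviors of that curtain matter
here: *shimmering*, the cascaded abdomen-flipping waves used against
predators, and *flickering*, the brief, apparently stochastic abdomen
flips of individual surface bees during quiescence. The analytical
question — do the nest zones that launch shimmering waves (trigger sites,
ts) flicker at higher intensity than the rest (non-trigger sites, nts),
and does arousal recruit additional trigger cohorts? — reduces to a video
measurement problem: extract sparse, 20–60 ms motion transients per
bee-sized patch of nest surface from long grayscale recordings, while
rejecting every other motion category (waves, fanning, walking, mouth-zone
traffic).

`beeshimmer` implements that measurement chain and the cohort statistics
on top of it. Since no raw field footage is deposited anywhere, the
package also contains a synthetic scene generator whose ground truth is
exact by construction; all validation in the test suite runs against it.

## Motion model

Motion between consecutive frames is measured as the unsigned per-pixel
luminance change, Δlum ∈ [0, 255]; 0 is motionlessness and 255 the
maximal attainable motion intensity. Color input is first reduced to luma
(Rec. 601 weights). A difference image can be segmented into a binary
motion mask at a configurable cut-off with three strength bands
(weak/medium/strong) for rendering; segmentation is presentational —
detection operates on the continuous square-level values.

The analysis unit is the *test square*: the grid cell of a superimposed
lattice whose side corresponds to one bee (15 mm; the two field setups
were 123 × 53 and 73 × 48 squares). Squares are indexed 0-based (row,
col), row 0 at the image top, with half-open pixel intervals, so every
interior pixel belongs to exactly one square; pixels beyond the last full
square are not gridded. The square-level statistic is the **mean**
absolute pixel difference over the square (a `sum` reducer is available).
The mean keeps square-level Δlum on the same 0–255 scale as pixels
regardless of image resolution, which makes the 2.0 detection threshold
resolution-independent; whether the original analysis used mean, sum, or
a masked-area statistic is not documented, so the normalized choice is
the default here.

The per-square difference series is indexed so that entry *t* (0-based)
is the transition between frames *t* and *t+1*; a series over *n* frames
has *n − 1* entries.

## Event model and interval filter

A flickering event on one square is a maximal run of series values
strictly above the detection threshold lasting 1–3 frames:

* `detect_threshold = 2.0` Δlum (strict `>`, matching the published
  operator);
* `max_duration_frames = 3` — 60 ms at 50 fps; longer runs are sustained
  motion (e.g. fanning produces wing patterns persisting over more than
  three frames) and yield *no* event;
* `min_gap_s = 1.0` — natural flickering typically repeats after more
  than one second, implemented as a refractory *merge*: a run whose onset
  falls within 1 s of the previous retained onset is folded into the
  earlier event (summed Δlum and peak absorb the repeat; onset and
  duration keep the earlier run's values). It is a merge rather than a
  requirement that events recur, so isolated events are never deleted.

The duration bound is defined in frames with the frame rate recorded in
the configuration; at 25 fps footage three frames correspond to 120 ms,
and whether the original 60 ms criterion was re-derived per frame rate is
unknown — users of 25 fps material should set `max_duration_frames`
deliberately.

Two exclusion mechanisms precede all statistics. First, *shimmering
episodes*: while a wave sweeps the nest, flicker detection is impossible,
so frames whose fraction of simultaneously supra-threshold squares is at
least `frac_threshold = 0.15` for at least `min_len_frames = 3` frames
are masked, and any event overlapping a masked frame is dropped. The
original study marked these intervals manually; the simultaneity fraction
automates the mask, and both constants are exposed because the right
values depend on wave geometry — a wave crossing a large nest may occupy
less than 15% of squares at any instant (the bundled `analysis/` workflow
uses fast waves for exactly this reason). Second, *mouth-zone masking*:
the high-traffic entrance region defeats the interval filter and is
excluded by a square mask (hand-drawn polygon outlines can be rasterized
by square centre, even-odd rule).

One caveat found while testing: the intuitive property "raising the
detection threshold can only reduce the event count" is true for
flicker-like traces but false in general — a higher threshold can split a
long, *rejected* sustained run into short, now-accepted fragments. The
property suite asserts monotonicity on sparse pulse traces only.

## Trigger sites and cohorts

Wave origins arrive as a registry (wave id, phase, source square) — in the
field derived by retrograde inspection of the footage, in synthetic mode
from the generator's ground truth. A trigger site is the source square
plus its 8 Moore neighbors, each assigned activity 1.0; neighborhoods are
clipped at nest borders (a corner source covers 4 squares) rather than
wrapped or renormalized, which keeps pooling additive. Pooled maps are
scaled to their per-phase maximum for rendering (white→red). The cohort
partition is scale-invariant: ts = active squares with pooled activity
> 0, nts = the remaining active squares, recomputed per experimental
phase (phases are explicit frame intervals in the run configuration;
pooling across phases is available and used for cohort comparisons that
need one fixed partition).

## Cohort statistics

Per square and phase with reference duration `t_ref` (taken as the
analyzed duration of the phase, since the original per-phase durations
are not published):

* rate = events / `t_ref` (kept in Hz internally; events/min only for
  display);
* intensity `fI = Σ sum_dlum / t_ref` (Δlum units per second; zero events
  give fI = 0);
* relF = fraction of nest squares with ≥ 1 event, overall and per cohort,
  with the number of nest squares as the common denominator so
  relF_ts + relF_nts = relF_ts+nts exactly.

Rates are compiled into 30 half-open classes of width 0.03 s⁻¹; rates at
or above 0.90 s⁻¹ are capped into the last class with a warning (the
original procedure is silent on overflow). Zero-rate squares are excluded
from compilation by default. Per class and cohort the mean fI, SEM
(sd/√n, reported as 0 when n = 1), and n are tabulated.

Class-mean curves are summarized as `y = a·e^(b·x)` fitted by ordinary
least squares of ln y on x (the spreadsheet-style fit contemporary with
the original analysis); a = e^intercept, b = slope, and R² is that of the
log-linear regression, computed directly from the residuals (R² ≡ 1 for
a constant-y or interpolating fit). Points with y ≤ 0 cannot enter the
log fit and are dropped with a warning. Class means rather than raw
records are fitted, following the compilation order of the procedure.
The rate–intensity association is tested with Spearman rank correlation
(mid-ranks, two-sided asymptotic P).

The ts/nts contrast uses the per-class signed difference
Δ_fI = mean fI(ts) − mean fI(nts) over classes populated by both cohorts;
zero differences enter neither sign group. The sign counts are tested
against equal expectation with χ² = (n₊ − n₋)²/(n₊ + n₋), df = 1, no
continuity correction — the plain goodness-of-fit form matching the
published positive-vs-negative comparison.

## The synthetic generator

The generator emulates exactly the statistical structure the analysis
assumes:

* **Flicker processes** are renewal processes per square: inter-event
  times are `min_gap_s` plus an exponential excess with mean
  `max(1/rate − min_gap_s, ε)`, so the long-run rate approaches
  `min(rate, 1/min_gap_s)`. A homogeneous Poisson process would violate
  the > 1 s repetition interval of natural flickering. Event durations
  are drawn from a distribution over 1–3 frames, amplitudes from a normal
  truncated below at 2.5 Δlum (just above the detection threshold), so
  "active cohort" means detectable by construction.
* **Rendering**: one filled ellipse (semi-axes 0.45 and 0.30 of the
  square side) per square on a uniform background. An event of duration d
  toggles the ellipse luminance at exactly d consecutive frame
  transitions, the shift sized so the square-mean |difference| equals the
  event amplitude; afterwards the level stands still, and toggles prefer
  returning toward the resting level so repeated events cannot ratchet
  into saturation. Frame differencing therefore recovers each event at
  its exact onset and duration — with zero noise, downstream recall and
  precision are exactly 1.0, which the acceptance suite asserts.
* **Waves** expand from a trigger square by Chebyshev distance at
  constant speed with Bernoulli participation — qualitatively the
  bucket-bridging propagation of real shimmering, without inventing
  dynamics.
* **Mouth zone**: squares that toggle every frame, producing sustained
  supra-threshold runs that the interval filter must reject.
* **Noise**: i.i.d. Gaussian per pixel and frame; frames are rounded and
  clipped to 8-bit (clipping raises a warning flag).

The whole scene is a pure function of its configuration including one
seed, so reruns are bit-identical; explicitly listed events are
seed-independent while pixel noise is not.

What the generator does *not* emulate — and hence what passing tests do
not show about real footage: bee appearance and occlusion, inhomogeneous
and changing illumination, camera shake (there is no registration step),
perspective distortion of the 3D bee curtain, and correlated sensor
noise. Recall of 1.0 on synthetic scenes validates the algorithmic chain,
not field performance.

## Problem sizes and numerical choices

The validation suite uses a study-scale scene of 73 × 48 squares at 4 px
per square, 3,000 frames at 50 fps with ~500 ground-truth events, noise
sd 0 and 0.5 Δlum — large enough to exercise the full pipeline while
keeping a complete test run within a few minutes. The statistical
recovery experiment uses 100 replicates of a 20 × 20-square design (200
ts squares with amplitude mean 8, 200 nts with 5, five rate groups from
0.06 to 0.42 s⁻¹, 60 s at 50 fps), evaluated at the event level without
pixel rendering since the rendering stage is validated separately.
At these conditions the sign/χ² procedure reports the designed ts > nts
contrast with P < 0.05 in every replicate.

Other numerical conventions, chosen once: 8-bit luminance with saturation
clipping; integer frame rounding of renewal onset times with a strict
post-hoc gap enforcement (> `min_gap_s · fps` frames between onsets);
pooled trigger maps scale by division only when a nonzero maximum exists
(an all-zero map stays zero); Spearman P-values are asymptotic
(`exact = FALSE`), appropriate at the n of binned analyses; and the
intensity-to-pixel-area conversion mentioned in the field description is
not applied — intensities are reported in Δlum/s, with the segmentation
mask available for users who need area units.

## Limitations

* Trigger registries must be supplied (or taken from synthetic ground
  truth); the package does not detect wave origins from imagery.
* The shimmering-episode mask is a global simultaneity heuristic; slow or
  spatially confined waves below `frac_threshold` will leak wave flips
  into the event table, as visible in the bundled demo's presentation
  phase.
* No tracking of individual bees: a square is a proxy for one bee, and
  two bees flickering in one square are indistinguishable from one
  faster-flickering bee.
* relF and the cohort statistics inherit whatever bias the mouth-zone and
  nest-contour masks carry; they are user inputs, not estimated.
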
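---
title: "Gaze-based cancellation testing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze-based cancellation testing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(etnt)
```

## The assessment

Visuospatial neglect (VSN) after a right-hemisphere stroke leaves patients
unable to orient to stimuli in the left half of space. The classic bedside
instrument is the cancellation test: the patient must find ("cancel")
every target among distractors on a display, and omissions lateralized to
the left indicate neglect. `etnt` implements a gaze-based variant in which
a target counts as found not by touch but when the patient's *point of
gaze* dwells on it — which additionally yields the full search path,
fixations and a map of explored space.

The package covers the whole measurement chain: stimulus boards, the
dwell-based detection rule, neglect indexes and search-strategy
classification, heat maps, clinical summary scores, and a generative
simulator of neglect-patient gaze used to validate every stage.

## Coordinate conventions

All positions are normalized to the unit square with the origin at the
**top-left** of the screen (x rightward in screen widths, y downward in
screen heights), the native convention of eye trackers. The patient is
seated centred on the screen, so hemifields are screen-referenced: *left*
means x < 0.5. Pixel geometry enters only through the aspect ratio:
detection zones are circular *on the physical screen*, so vertical
distances are rescaled by height/width before comparing against a radius
expressed in screen widths. Timestamps are seconds since test start;
devices reporting millisecond ticks must be converted at ingest, because
every threshold in the package is in seconds.

## The stimulus board

The standard display holds 60 stimuli — 20 targets and 40 distractors —
split equally into 30 per hemifield (10 targets, 20 distractors each
side), uniformly distributed. A practice display uses 4 targets and 8
distractors. Distractor shape is not modelled; `kind` carries the only
semantic distinction.

"Uniform" is realized as per-side rejection sampling with a hard minimum
centre distance equal to the zone diameter, which guarantees that
detection zones never overlap, so a gaze sample can dwell in at most one
zone. Two further constraints keep the geometry clean: a margin (default
0.05) keeps stimuli off the screen edges, and a guard band (default half
a zone diameter) around the vertical midline prevents stimuli whose
hemifield would be ambiguous. Feasibility is checked before sampling with
an area heuristic (total zone area at most 60% of the placeable area);
tighter configurations fail fast rather than loop. Generation is
deterministic given a seed.

```{r board}
board <- generate_board(board_config(seed = 42))
board_summary(board)
```

## The detection rule

A stimulus is tagged when gaze is held for at least `dwell_s` seconds
(default 0.4) within a circular zone of diameter `zone_diameter` (default
0.07 screen widths, i.e. 7% of screen width) centred on it — the
dwell-time selection convention of gaze-interaction research. Two
interpretation choices deserve note:

* **Dwell is contiguous.** "Maintaining" gaze is read as an uninterrupted
  hold: a run of consecutive *valid* samples, all in-zone, whose time span
  (last minus first timestamp, so irregular sampling is handled) reaches
  the threshold. Blinks and excursions reset the clock. A cumulative
  moving-window alternative would tag more liberally; it is deliberately
  not implemented.
* **One tag per stimulus.** Re-visits add to the stimulus's total dwell
  but never produce a second event, mirroring a mark once circled.

Samples exactly on the zone boundary count as inside. Because zones are
disjoint by construction a sample cannot belong to two zones, but
defensively the nearest centre wins. The tag time is the moment the first
qualifying run attains the threshold, quantized to the sample grid.

The implementation is validated against an exhaustive sliding-window
oracle (every contiguous in-zone run of every stimulus, checked
independently) on hundreds of randomized recordings, and against
monotonicity laws: lowering the dwell threshold or enlarging the zone can
only ever add tags.

Fixations for search-path drawing use a standard dispersion-threshold
(I-DT) algorithm: maximal windows whose x-range plus y-range stays within
a dispersion bound (default: the zone diameter) and whose duration
reaches 0.1 s. Fixation extraction is a visualization aid; detection never
depends on it.

## Indexes, strategy, heat maps

`score_test()` reduces one administration to the index set used in
neglect assessment: located/missed targets per hemifield (count
conservation per side is a tested invariant), test duration, mean
time-to-tag over located targets ("latency"), mean distance between
consecutively tagged targets ("proximity"), and a bounded laterality
index

$$ LI = \frac{located_{right} - located_{left}}{located_{right} + located_{left}} \in [-1, 1], $$

0 for side-symmetric performance and +1 when only right-field targets are
found (left neglect). The original touch-screen instrument's proprietary
"neglect score" formula is unpublished; LI is this package's documented,
testable substitute, *not* a claimed reimplementation, and the same
caveat applies to latency and proximity. Degenerate cases carry NA flags:
latency needs at least one located target, proximity two; LI is defined 0
when nothing is located. Mirroring board and gaze about the midline
negates LI, so the toolkit serves right-neglect data unchanged.

Search behaviour is summarized two ways. The *start sector* is the screen
quadrant of the first fixation that lands in any stimulus zone (fallback:
first fixation overall; points on a split line resolve upward/rightward).
The *scan strategy* classifier contrasts the two canonical patterns —
neglect patients typically start at the right edge and scan leftward in
vertical columns, controls read left-to-right top-down — by comparing
median absolute inter-tag steps along x and y with the Spearman trend of
tag order against x (resp. y); thresholds of |rho| >= 0.5 and at least 4
tags keep the label `"other"` for anything ambiguous.

Heat maps accumulate valid gaze time on a 32 x 18 grid (a cell is then
2.5% of screen width — finer than a zone, coarse enough to fill at
clinical recording lengths): each inter-sample interval is credited to
its leading sample's cell, so the grid total equals the recording's valid
time exactly (tested to 1e-9 relative). Off-screen samples, which occur
under calibration distortion, clip to edge cells. Post-minus-pre
difference maps subtract cellwise; positive cells mark newly explored
space.

## Clinical scores

**Anosognosia index.** Patients rate their own performance on K subtests
(study design: 6) on a 1–5 Likert scale; an examiner rates the same
subtests. The index is the mean signed discrepancy scaled by the maximal
per-item discrepancy of 4:
$$ AI = \frac{1}{4K}\sum_{k=1}^{K} (external_k - self_k) \in [-1, 1]. $$
AI < 0 iff the patient's self-ratings exceed the examiner's on net —
self-overestimation, the behavioural signature of anosognosia. The sign
law (AI < 0 exactly when the self sum exceeds the external sum) and the
bounds are tested exhaustively on small rating grids. The 1/(4K)
normalization is this package's choice of scale; a raw-mean variant
(divide by K only) is available via `normalization = "mean"`.

**Feasibility.** A training diary records one row per completed session.
Adherence is completed sessions as a percentage of the maximum (protocol:
15), rounded half away from zero — 14 of 15 gives 93%. Attrition is
dropouts over enrolled; medians and IQRs use midpoint interpolation
(quantile type 2), the convention that reproduces integer medians on
small cohorts.

**Effect sizes and exact tests.** Nonparametric effect size follows
r = z/sqrt(n) with n the observations entering the test, banded at
0.1/0.3/0.5 (small/medium/large, boundaries inclusive upward).
`paired_compare()` is a Wilcoxon signed-rank test: zero differences
dropped, midranks on ties, and — because neglect cohorts are small — an
*exact* two-sided p by enumerating all 2^m sign assignments for m <= 12
(doubled smaller tail, capped at 1), falling back to the normal
approximation without continuity correction above that.
`repeated_compare()` is the tie-corrected Friedman test with an exact p
by enumerating all (k!)^s within-subject orderings for s <= 8 subjects.
All-zero differences (or identical columns) return p = 1 by convention
with an undefined-flag statistic. Both exact routes are tested against
independent brute-force enumeration oracles and against the `stats`
implementations on tie-free data.

## The gaze simulator

The simulator exists so the whole chain can be validated without patient
recordings; it is a *behavioural caricature*, not an oculomotor model.
A virtual patient is parameterized by:

* **Omission gradient** — each stimulus is omitted with probability
  $P(\text{omit}\mid x) = \operatorname{logit}^{-1}(\beta_0 + \beta(0.5 - x))$,
  the simplest monotone-in-hemifield model: beta >= 0 concentrates
  omissions leftward, beta0 sets severity. Defaults beta0 = -2, beta = 4
  give roughly 27% omission at the typical left-target position and 5% on
  the right — a moderate left neglect.
* **Search strategy** — visit order over non-omitted stimuli is
  column-wise from the start side (`vertical-leftward`, start right by
  default) or row-wise top-down (`horizontal-top-down`), with 8 spatial
  bins.
* **Dwell** — found targets are held for a normal draw (mean 0.6 s,
  sd 0.1 s) clamped from below at the detection threshold plus two sample
  periods, so every intended find is detectable; distractors and visited
  non-targets get a uniform glance of 20–50% of the threshold, which can
  never tag. Saccades are linear at 1.5 screen widths/s; a validation
  error rejects speeds slow enough that merely crossing a zone could
  approach the dwell threshold.
* **Sensor model** — Gaussian jitter (default sd 0.01, versus a zone
  radius of 0.035) is added to true gaze, then an affine calibration
  distortion (gain about screen centre plus offset) maps true to
  *reported* gaze, then Poisson-seeded geometric bursts of invalid
  samples emulate blinks and track loss. Eye-tracker calibration is
  emulated only at this phenomenological level.

Three properties anchor the simulator to the scoring chain and are tested
across many seeds: with zero noise, identity calibration and no blinks,
detection recovers the ground-truth found set *exactly*; empirical
omission frequencies match the logistic model (Monte-Carlo against the
binomial CI); and calibration bias beyond the zone radius degrades
detection, reproducing the calibration-failure phenomenology reported for
low-cost trackers.

Because ground-truth omissions are Bernoulli draws from the stated
logistic model, the gradient is recoverable: `recover_gradient()` pools
per-target outcomes over reports and fits a maximum-likelihood logistic
regression on 0.5 - x. On 200 simulated tests the generating (beta0,
beta) are recovered within 3 standard errors, and under a beta = 0 truth
the slope's Wald test at alpha = 0.01 stays non-significant in at least
95% of replicate batches — the package's parameter-recovery acceptance
surface. Batches of 25–200 tests at 30 Hz keep these experiments in the
tens of seconds; the test suite and the acceptance script state the sizes
they use.

`simulate_cohort()` wraps this into a pre/post design: per-patient
intercept heterogeneity (sd 0.5), a training effect expressed as a
downward shift of beta0 at post, and a synthetic training diary to
exercise the feasibility summaries on the same fixture.

```{r cohort}
cohort <- simulate_cohort(
  7, board,
  profile = neglect_profile(noise_sd = 0, blink_rate_hz = 0),
  effect_shift = 1, attendance = c(15, 15, 14, 14, 13, 12, 10),
  sample_rate_hz = 30, seed = 7)
located <- vapply(cohort$patients,
                  function(p) c(pre = p$report_pre$located_total,
                                post = p$report_post$located_total),
                  numeric(2))
located
feasibility_summary(cohort$diary)[c("adherence_median_pct",
                                    "attrition_pct", "sessions_median")]
```

## What passing tests do and do not show

The simulator emulates right-start columnar search, a lateralized
omission gradient, near-threshold dwells, blinks and affine calibration
error. It does **not** emulate saccadic dynamics (main-sequence
velocities, undershoot), smooth pursuit, pupil-size artefacts,
re-fixation behaviour, fatigue drift, or nonlinear calibration warp.
Green tests therefore certify the *scoring pipeline* — detection rule,
indexes, statistics, round trips — under controlled conditions; they are
not evidence about any particular patient population. Real-data caveats
from the instrument's own feasibility work remain: low-cost tracker
calibration is error-prone, and gross bias shows up in these analyses as
clustered off-target gaze and collapsed detection counts, which is
exactly the behaviour the calibration-bias tests reproduce.

## Numerical choices and degenerate inputs

* Zone membership uses `<=` (boundary inside); tag times inherit the
  sample grid, so assertions about them should allow one sample period.
* Empty recordings score as zero-duration tests with empty tag lists;
  empty boards yield empty summaries with NA minimum distance.
* Heat-map binning floors to cells and clips off-screen samples; bin
  counts must be positive.
* Exact-test comparisons use a 1e-9 slack when comparing rank statistics
  to avoid floating-point ties.
* The screen centre classifies as upper-right by the documented
  tie-break; Spearman correlations on constant sequences return NA and
  fall through to `"other"`.
* Report JSON writes NA indexes as null and validates required keys on
  read, naming anything missing.

## Known limitations

The laterality index, latency and proximity are documented substitutes
for unpublished originals, so absolute values are not comparable across
software, only within. The stop rule of the live test (patient announces
completion) has no computational analogue — test duration is simply the
recording span. The simulator's kinematic defaults are placeholders:
recovery experiments validate internal consistency, not biological
realism. And group-level results from any specific patient cohort are
outside what synthetic validation can reproduce.
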
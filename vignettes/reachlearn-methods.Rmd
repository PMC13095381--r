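---
title: "Methods: reach segmentation, outcome scoring and learning statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reach segmentation, outcome scoring and learning statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`reachlearn` analyses the single-pellet skilled-reaching task from
markerless pose-estimation output. This vignette documents the models and
procedures the package implements, the parameters that matter, the design
choices that were genuinely open, and what the synthetic-data generator
does and does not emulate.

## Coordinate and data conventions

All modules share the native convention of 2D pose-estimation output:
image pixel coordinates with the origin at the top-left, y increasing
downward, and 0-based frame indices. A pose table holds one row per video
frame with `x`, `y` and a likelihood in [0, 1] for each of the four
tracked points (left paw, right paw, nose, pellet), under three stacked
header rows (scorer / bodyparts / coords). Within a session, trial `t`
occupies frames `(t-1)*F` to `t*F - 1`, with `F = round(access_window *
fps)` (default 13 s x 240 fps = 3120 frames).

## Filtering

Every tracked point is filtered by a likelihood cutoff (`p_cutoff`,
default 0.85) and the reach-detection paw additionally by rectangular
tracking bounds covering the region outside the slit. Two boundary
decisions were open and are resolved as follows: a sample whose likelihood
*equals* the cutoff is retained (the exclusion rule is "falling below"),
and points on the bounds edge count as inside. Filtering keeps original
frame indices, so gaps in the retained sequence encode occlusions.
Occluded frames arrive with near-zero likelihoods rather than missing
rows, because the upstream tracker labels every frame.

No temporal smoothing is applied anywhere in the analysis: filtering is
purely a likelihood/bounds selection, and all kinematics run on raw
retained coordinates. Display functions may spline-interpolate trajectories
for visual clarity, but never the metrics.

## Reach detection

A reach is a paw excursion that crosses the slit outward and subsequently
retracts. Detection runs on the filtered paw track with a
directional-vector consensus rule (`detection_params()`):

- **window** = 5 step vectors between consecutive retained samples,
- **consensus** = 4 of those 5,
- **min_points** = 6 samples per reach,
- **max_gap** = 5 frames (about 21 ms at 240 fps) between adjacent retained
  samples.

"Toward the pellet" is formalised as a strict decrease of the Euclidean
distance to the static per-trial pellet coordinate. This reading is
parameter-free and rotation-invariant, and reduces to the obvious
along-x reading when the pellet lies on the reach axis; a zero-length step
(or one that leaves the distance unchanged) counts as neither toward nor
away. The scan marks the earliest sample whose window reaches toward-
consensus as a reach start, then the earliest subsequent sample whose
window reaches consensus in the opposite predicate (distance strictly
increasing) as the retraction onset, which is the reach endpoint; scanning
resumes at the sample after the endpoint, alternating until the track is
exhausted. Ties are broken by the earliest index at both ends, and
candidates shorter than `min_points` are discarded.

Three consequences of this rule are worth knowing:

- The same windowed rule is applied symmetrically to the end detection,
  including the adjacency requirement (`max_gap` breaks a window), so
  reaches are never stitched across long occlusions.
- For a perfectly monotone approach-then-retreat excursion, the 4-of-5
  consensus fires one sample *before* the geometric apex (4 of the 5
  vectors in that window already recede), so the detected retraction onset
  sits one sample short of the apex, and a minimal 6-up-6-down excursion
  yields a 5-sample candidate that the length rule discards. The test
  suite freezes this behaviour against an exhaustive brute-force oracle.
- The reach's point sequence runs from start to retraction onset
  inclusive; the retraction limb is not part of the reach for kinematics.

The detection paw defaults to the configured reaching paw; with
`paw = "auto"` each session uses whichever paw retains more in-bounds
high-likelihood samples, a proxy for paw preference.

## Kinematics

Per reach, on the reach interval only:

- **path length** (px): the sum of Euclidean step lengths along the point
  sequence. "Distance of a reach" is read as total path length rather than
  endpoint displacement because it is the standard trajectory-length
  measure and is sensitive to meandering, poorly directed reaches; the
  chord variant is available via `distance_metric = "chord"`.
- **ΔY** (px): max(y) − min(y), the vertical spread.
- **ΔX** (px): the maximum of `toward_sign * (x − slit_x)`, floored at 0 —
  how far the paw extends beyond the slit plane; a paw behind the slit
  contributes nothing.

Aggregation averages within subject-day first (matching the
repeated-measures design downstream); a subject-day with zero reaches
yields a missing value, not a zero, and propagates to the statistics stage
as missing data.

## Outcome taxonomy and denominators

Labels: `success` (retrieval through the slit), `complete_miss` (no
contact), `contact_miss` (contact, no retrieval), `vain` (reach while no
pellet is present), `other` (residual). All labels except `vain` are
*targeted* reaches. A trial with no reaches is a *No Try*; at most one
success per trial is possible because retrieval removes the pellet, and
the scorer validates both constraints.

Denominator decisions, where the convention was open:

- success-by-trial: successful trials / *attempted* trials (No-Try trials
  excluded);
- success-by-reach, complete-miss and contact-miss percentages: over
  targeted reaches ("other" reaches are targeted, so they stay in this
  denominator);
- vain percentage: over total reaches;
- first-reach success: trials whose ordinal-1 reach succeeded, over
  attempted trials — chosen so the metric is comparable side by side with
  trial-level success;
- final-day outcome distributions pool reaches across the subjects of a
  group (per-subject weighting is available as an option).

All rates return missing values on zero denominators, never errors, and
the partition identities (success + complete + contact + other = targeted;
targeted + vain = total) are asserted property-style in the tests.

The optional geometric classifier (`auto_classify_reach()`) substitutes
for manual scoring when no annotations exist: pellet absent at reach start
→ vain; minimum paw-pellet distance above `contact_radius_px` (default
15 px) → complete miss; contact followed by a sustained pellet-likelihood
collapse within `retrieval_lag` frames of the retraction onset (default
25, covering a retraction at 240 fps; "sustained" means at least 30% of
the lag window, so a single-frame occlusion does not mimic removal) →
success; contact without removal → contact miss. It never emits `other`,
so the residual manual category bounds its achievable agreement.

## Learning statistics

**Learning Index.** Per animal, the difference in a metric between the
first and last training day, oriented so that positive always means
improvement: `day1 − day8` for metrics that decrease with learning (miss
and vain percentages, path length, ΔY, ΔX), `day8 − day1` for success-type
metrics (`li_orientation()` is the registry). An animal missing either
endpoint day gets a missing index and is excluded from group tests, with
the exclusion count reported.

**Paired Day-1 vs Day-8.** The normality gate is applied to the paired
*differences* (the natural unit of a paired test), with a Shapiro–Wilk
threshold of 0.05 (configurable): normal-looking differences get a paired
t test, otherwise a Wilcoxon matched-pairs signed-rank test. The branch
taken is recorded in every result. All-zero differences short-circuit to
the exact null result (statistic 0, p = 1) rather than erroring on zero
variance.

**Group contrasts.** Welch's unequal-variance t test, two-sided, with a
degenerate fast path when both groups are the same constant.

**Longitudinal models.** `longitudinal_model()` branches purely on the
data: a complete subject × day table gets a repeated-measures two-way
ANOVA (split-plot strata, subject as the repeated unit), with a
Greenhouse–Geisser epsilon computed from the pooled within-group
covariance of the subject × day matrix via orthonormal contrasts and
applied to the within-subject terms (day, group × day) — this is what
produces fractional numerator degrees of freedom. Any missing cell
switches to a linear mixed model, `value ~ group * day + (1 | subject)`
with day categorical and Satterthwaite F tests (lmerTest). The
between-subject F of the repeated-measures branch is cross-checked in the
tests against the independent one-way ANOVA on subject means. Any column
(genotype, condition, sex) can serve as the between factor. Tests are
two-sided throughout and no multiple-testing correction is applied across
metrics; reports state the branch and epsilon so the route is auditable.

## The synthetic-session generator

The generator exists so that every downstream stage can be tested against
exact ground truth. Its defaults emulate the study conditions: 8 days x
50 trials, 13 s access windows at 240 fps, two mixed-sex groups of 10
subjects, a static pellet in a divot ~60 px beyond the slit plane, and
occlusion dropout that emits near-zero likelihoods rather than deleting
rows.

**Outcome model.** `success_prob_curve` is the *per-attempt* (per targeted
reach) success probability, `p(day) = baseline + (asymptote − baseline) *
(1 − exp(−rate * (day − 1)))`, so the configured asymptote lives on the
success-by-reach scale (defaults 45% for the reference group, 25% for the
impaired group, with low day-1 baselines — the plateau range typical for
this task). Attempt counts are `1 + Poisson(attempts_lambda)` capped at
`max_attempts`; attempts stop at the first success because retrieval
removes the pellet, which also makes at most one success per trial a
structural property. Failed targeted reaches split into complete miss /
contact miss / other at fixed weights (0.55 / 0.40 / 0.05; the small
residual mirrors the minor "other" slices of final-day outcome
distributions). Vain reaches occur only after a within-trial retrieval
(the pellet is otherwise present for the whole window), with probability
`vain_rate` per retrieval trial. No-Try trials occur at a constant
per-trial rate. Attempt counts and inter-reach spacing are free
parameters of the generator, not estimates of any real cohort.

**Trajectory model.** Each reach is built in polar coordinates around the
pellet: the radius shrinks linearly from the start distance (just beyond
the slit, at pellet height) to the apex distance while the bearing sweeps
from the slit direction to the apex direction, followed by a mirrored
retraction. Retrievals and contact misses touch the pellet at the apex;
complete misses place the apex beyond the pellet in x by the day's
overshoot value with a ±30 px lateral aiming error, sweeping a curved,
poorly directed path. This construction guarantees a unimodal paw-pellet
distance profile — every outward step strictly approaches the pellet,
every retraction step strictly recedes — which is the geometry the
consensus detector's "retraction onset" semantics presuppose (a straight
line to an overshot target would make the distance profile non-monotone
and the notion of a single retraction onset ill-defined). Gaussian jitter
is added on top: horizontal noise (`noise_sigma`) and vertical spread
(`vspread`), both decreasing linearly across days, with the impaired
group decaying more slowly. Reaches are placed in per-event slots wide
enough that ground-truth intervals never overlap.

**What it does not emulate.** Digit and grasp kinematics, pellet physics
after contact (removal is modelled as a likelihood collapse only),
camera-angle distortion, paw-preference switching, inter-trial wait
periods, and realistic attempt-count distributions. Passing tests
therefore demonstrate that the algorithms are correct on data with the
assumed structure (unimodal excursions, static pellet, conservative
occlusions), not that detection is robust to every pathology of real
video; on real data the likelihood filter and `max_gap` adjacency rule
carry that burden.

**Determinism.** One integer seed fixes the whole cohort. Pose tracks are
rendered lazily per subject-day from a sub-seed derived deterministically
from the cohort seed, so a 20-subject cohort (≈ 5 million frames per group
per day block) never needs to reside in memory at once, statistics-only
studies can skip trajectory rendering entirely, and `write_cohort()`
reproduces identical files byte for byte.

## Numerical choices and degenerate inputs

- Pose tables serialise with 12 significant digits, giving write→read
  round trips well below 1e-9 relative error while keeping files
  byte-stable across runs.
- Tracks shorter than `min_points` yield an empty reach table, not an
  error; empty reach sets yield all-No-Try trial tables; all rate
  functions return missing on zero denominators.
- The Greenhouse–Geisser epsilon is clamped to its theoretical range
  [1/(d−1), 1].
- Exact-tie handling: boundary likelihoods are retained; zero-length steps
  vote for neither direction; earliest-index tie-breaks in detection.

## Problem sizes used by the test suite

The property suite runs the detector-oracle equivalence on 1,000 random
tracks (up to 200 samples), ground-truth recovery on a clean 2 x 5-subject
x 8-day x 20-trial cohort at full 240 fps resolution, statistical power on
100 replicate cohorts with the default 45% vs 25% asymptote gap, type-I
calibration on 200 replicate null cohorts, and the ΔY Learning-Index
contrast on 100 replicates of 25 reaches per subject-day endpoint. These
sizes keep Monte-Carlo error well inside the asserted margins.

## Known limitations

- 2D analysis only; depth-wise motion is invisible to every metric.
- The detector assumes a single static pellet reference per trial; a
  pellet that rolls after contact will bias the toward/away predicates
  near contact.
- The geometric classifier cannot produce the manual "other" category and
  relies on a clean pellet-likelihood signature of retrieval.
- The repeated-measures branch requires a complete table; a single missing
  cell switches the whole analysis to the mixed model (by design, but the
  two branches answer subtly different questions when data are missing not
  at random).
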
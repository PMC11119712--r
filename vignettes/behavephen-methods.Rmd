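---
title: "Methods: behavioural phenotyping pipelines and their synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioural phenotyping pipelines and their synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(behavephen)
```

# Scope and data model

`behavephen` scores four behavioural assays used to phenotype knock-in
Huntington-disease mouse cohorts (heterozygous mutants against wild-type
littermates, split by sex and by disease stage: premanifest at 2–3 months,
manifest at 9–12 months):

* a one-hour **open-field** session, from a markerless-tracker keypoint
  table plus a per-frame behaviour label stream;
* the **accelerating rotarod** (5–40 rpm over 300 s, 3 trials/day over
  4 days), from annotated rotation/recovery/fall events and hind-paw height
  traces;
* a **water T-maze** (acquisition, probe, reversal, swim tests), from the
  body-centre trajectory through maze ROIs;
* a home-cage **lever-pulling task**, from the RFID-stamped operant event
  log.

Inputs arrive as the formats those instruments actually emit (wide
three-header or long pose CSVs, label CSVs, plain-text event logs, YAML
geometry configs) and are converted once, at load, into validated S3
containers (`pose_track`, `label_stream`, `cohort`, trial objects). All
coordinates are calibrated to centimetres at load (`px_per_cm`), with the
image convention (y down, 0-based frames), so no downstream code ever mixes
units.

Because the animal recordings behind the assays are not distributable, the
package carries a first-class synthetic-data generator that emulates all
four input kinds with known, planted structure. Every analysis stage is
therefore testable against exact ground truth at desk scale.

# Open field

Distance is tracked through the tail-base keypoint: per-frame Euclidean
steps, summed into 5-min bins. Habituation — the decline of exploratory
locomotion across the session — is expressed as the percent change of each
bin against the first, `100 (d_i - d_1)/d_1`, which is identically zero in
bin 1 and negative under habituation. A decay rate is estimated by the
log-linear fit `log d_i = log d_1 - lambda (i-1)`.

Label analysis collapses the classifier vocabulary to four classes
(locomotion/turning combined — animals alternate between them — sniffing,
rearing, other). Bouts are maximal runs of one label, with a configurable
gap-merge (`gap_tol_s`) and minimum duration (`min_bout_s`), both default 0.
Rearing is scored *away from the wall*: rearing frames within
`wall_margin_cm` (default 2 cm) of a wall are relabelled before fractions
and bouts are computed. The centre zone is the centred square of 50% linear
extent (19 × 19 cm in the 38-cm arena). The source protocols do not define
the centre zone or wall margin numerically; both defaults are common
conventions and are configurable. Which keypoint anchored centre-time in the
original analyses is likewise unstated; we default to the tail base and
expose the choice.

Missing tracking: frames with confidence below 0.6 are dropped; gaps up to
0.5 s are linearly interpolated, longer gaps stay missing and contribute
zero distance (and are counted). This mirrors standard tracker
post-processing; the thresholds are arguments of `read_pose_table()`.

# Accelerating rotarod

Two protocol semantics are implemented exactly:

* **Standard** — one rotation is equivalent to a fall: latency is the first
  rotation or the fall, whichever is earlier.
* **Rotations Allowed** — the trial survives rotations until three occur
  *consecutively*; we operationalise "consecutive" as a run of rotations
  uninterrupted by a recovery event (the event annotator supplies recovery
  marks; the protocol text does not quantify the term). Latency is the third
  rotation of such a run, or the fall.

On any event sequence, Standard latency ≤ Rotations-Allowed latency; a
trial with no terminating event scores the 300-s cap.

Paw slips are excursions of one or both hind paws below the rod bottom. An
event opens when either paw crosses `rod_bottom - min_depth_cm` (default 0:
any crossing counts, since no minimum excursion depth is documented) and
closes when **both** paws are back above the rod; events separated by less
than `merge_window_s` (0.2 s) merge, preventing double counts from
threshold jitter. Slip rates are slips per minute; trials shorter than 20 s
are excluded from slip-frequency analysis rather than scored.

**Weight normalization.** Manifest mutants are markedly lighter than
littermates, and weight itself depresses rotarod latency; raw latencies
therefore flatter the mutants. Normalized latency multiplies time on the
rod by `weight / reference`, where the reference is the mutant-group mean
weight of the same sex × age cohort. The factor is 1 at the reference
weight. Premanifest cohorts, which show no weight phenotype, are analysed
raw.

# Water T-maze

The maze is modelled as a cross of rectangles: long North/South arms
(37 cm), short East/West choice arms (21 cm), 10-cm arm width, and the
junction square (side = arm width) as the **decision point**. The exact
pixel extent of the decision box used with the original tracker is not
published; the junction square is the natural geometric reading and is what
we use. ROI tests use the centroid of available keypoints.

* **Time to platform**: first frame entering the platform zone (distal
  10 cm of the choice arm) and staying ≥ 1 s — the dwell requirement kills
  swim-through false positives. Times over 30 s are capped at 30 s and
  flagged `guided` (the experimenter guides such trials).
* **Normalized time** divides by `weight / reference` (heavier animals swim
  slower; wild-types show a positive weight–time correlation), manifest
  cohorts only.
* **Arm entries** count junction→choice-arm transitions with a 1-cm
  hysteresis band to de-bounce boundary oscillation (entries were scored
  manually in the original protocol; the band makes automated counting
  robust).
* **Decision-point dwell** is the percentage of trial frames inside the
  junction square.
* **Accelerations** count stop→start cycles of the smoothed speed
  (0.2-s boxcar): a stop is < 2 cm/s sustained ≥ 0.25 s, a start exceeds
  6 cm/s; the initial start of swimming counts as one, and an
  all-stationary track scores zero. The thresholds the original
  tracker-based analysis used are unpublished; ours are configurable
  defaults chosen well inside the gap between floating jitter (< 1 cm/s)
  and cruise swimming (~20 cm/s).
* **Probe strategy**: starting from the arm opposite to training, entering
  the trained arm's location is allocentric (place learning); entering the
  mirrored arm — repeating the trained body turn — is egocentric (response
  learning). A probe with no arm choice is excluded.
* **Reversal eligibility**: ≥ 2 of the 3 day-3 acquisition trials reached
  the platform in one arm entry without guidance.
* **Swim speed**: start-of-South-arm to maze centre (37 cm) over the
  elapsed time; the mean of trials 2 and 3 is reported, trial 1 discarded.

# Lever-pulling task

The task runs as a three-phase state machine per mouse. Phase 1 habituates
nose-poking: a water drop rewards the *first* nose-poke of each fixed
15-min window (the protocol wording is ambiguous between per-poke and
per-window reward; we adopted the windowed reading, with the window length
configurable). After the 100th rewarded poke the mouse moves to phase 2,
where a pull strictly beyond 8° of the 25° lever range is a success; after
the 100th success, phase 3 rewards pulls whose peak angle lies in the
12–21° goal band, closed at both ends (whether 21° itself counted is
unstated; the closed band is the plain reading and both boundaries are
configurable). Transitions apply from the next trial. Before any of this, a
refinement pass drops trials with angles outside 0–25°, non-finite
readings, or timestamps running backwards for a mouse.

Phase-3 trials are organised into half-open 24-h bins anchored at the first
phase-3 trial (clock-day binning is the alternative reading; the anchored
bins keep day 1 complete for every mouse). Each bin reports trial counts
and percent success; empty interior bins are emitted with `n = 0`. Testing
stops at 16 (± 2) completed phase-3 days or 60 total days, whichever comes
first. Learning curves are summarised by least-squares fit of
`floor + (ceiling - floor)/(1 + exp(-rate (day - midpoint)))` to the pooled
per-day success rates; pooled trial counts rather than mean-of-mice rates,
because pooling weights days by evidence and halves the variance of the
recovered rate.

# Statistics

Group comparisons follow the original analysis suite: two-way ANOVA with a
between factor (genotype) and either a second between factor (sex) or a
within factor (day/bin); Sidak-corrected pairwise contrasts
(`p_adj = 1 - (1-p)^m`); two-tailed pooled-variance t tests; Pearson
correlations with t-based p-values; and Fisher's z test,
`z = (atanh r_1 - atanh r_2)/sqrt(1/(n_1-3) + 1/(n_2-3))`, to compare two
correlations.

Design choices the source leaves open: for unbalanced fully-between designs
we use type-III sums of squares with sum-to-zero contrasts, matching the
behaviour of the commercial packages this field uses; repeated-measures
designs use the classical univariate split-plot partition (between effect
against the subject stratum, within and interaction against the
within-subject residual), without a sphericity correction. Missing values
make that partition ill-defined; the package then analyses available cases,
warns, and labels the result a *mixed-effects approximation* — full REML
mixed models are deliberately out of scope. An exactly constant response is
reported as F = 0, p = 1 rather than as 0/0 floating-point dust.

# The synthetic testbed

`effect_spec()` fixes the study conditions in one validated object;
`gen_cohort()`, `gen_open_field()`, `gen_rotarod_trial()`,
`gen_tmaze_trial()` and `gen_pipaw_log()` generate the four input kinds
with planted ground truth. Defaults emulate a manifest male cohort:

* **Cohort** (12 mutants vs 15 wild-types by default): weights normal with
  wild-type mean 42 g (centre of the reported wild-type range), SD 4 g, and
  the mutant mean offset 10.48 g below — the reported manifest male
  deficit. The offset is applied at manifest age only.
* **Open field**: per-bin distance `d_1 exp(-lambda (i-1))` with lognormal
  session noise (SD 0.1) around a 2000-cm first bin (~20 m per 5 min, a
  typical exploring mouse); decay 0.08/bin for wild-types and 0.03/bin for
  mutants encodes the habituation deficit. The trajectory is a bounded
  correlated random walk (turning-angle SD 0.3 rad/frame, reflecting walls)
  whose per-bin path length matches the planted profile; labels come from a
  semi-Markov chain (independent bout draws, geometric durations) whose
  stationary time fractions have the closed form `e_j m_j / sum(e m)`;
  mutant males get a higher rearing emission and longer rearing bouts.
* **Rotarod**: latency = (80 + 25·(day−1)) s × genotype factor (mutant
  0.85) × `(reference_weight/weight)^1` × lognormal noise, truncated to
  5–300 s; slips planted at 7.5/min (wild-type) vs 8.1/min (mutant, the
  reported direction) as 0.3-s, 0.5-cm sub-rod excursions with ≥ 0.6-s
  spacing so the detector's merge window cannot fuse two planted events.
* **T-maze**: swim speed 19.5 cm/s (the reported group mean) scaled by
  `(reference_weight/weight)^1`; correct-choice probability rising linearly
  from 0.5 to 0.95 (wild-type) or 0.80 (mutant) across the nine acquisition
  trials; decision-point dwell gamma-distributed (mean 1.2 s wild-type,
  2.0 s mutant); planted stop/start pauses (Poisson mean 2 vs 2.5,
  duration 0.6–1.2 s) on a spaced grid along the approach arm. Durations
  are floored at 0.6 s because a stop shorter than the detector's smoothing
  window plus minimum-stop time (~0.45 s) is not a well-posed planted
  event. Tracker noise defaults to zero for this task so ROI-crossing
  frames are exact and ground-truth comparisons at ± 1 frame are
  meaningful; a noise parameter exists.
* **Lever task**: phase-3 success probability
  `0.10 + 0.30/(1 + exp(-rate (day - 6)))` with rate 0.45/day (wild-type)
  vs 0.22/day (mutant) — slower learning to a comparable ceiling, the
  reported pattern; 200–400 trials/day (the reported engagement), phase-2
  angles N(10°, 4°) truncated to the lever range.

**Weight acts only through the explicit multiplicative couplings above.**
That design makes the normalization procedures testable against a known
mechanism: multiplying latency by `weight/reference` (or dividing T-maze
time) inverts the planted factor exactly, so on cohorts where performance
varies only through weight the weight–performance correlation must shrink
toward zero — and does, in 50/50 seeded cohorts.

Reproducibility: every generator draws from a child seed obtained by a
stable 31-bit hash of (master seed, animal id, task, trial indices), so one
animal's data are independent of what else was generated, and a fixed seed
reproduces all outputs byte for byte.

What the generator does **not** emulate: biomechanics and posture (labels
are independent of position, so wall-rearing correction is exercised only
by construction-level tests), thigmotaxis (occupancy is near-uniform, so
synthetic centre time sits near the 25% area ratio rather than the lower
values wall-hugging mice show), inter-trial correlation beyond the planted
curves, circadian structure in the home cage, and experimenter guidance
dynamics. Passing tests therefore certify the *computations*, not the
biology: on real data the detectors face tracker noise and ambiguous
events the synthetic inputs deliberately exclude.

# Numerical choices and degenerate inputs

Seconds-to-frames conversions use a 1e-9 guard before floor/ceiling so that
an exact multiple of the frame period never rounds across a frame. Bout
gap-merging applies before the minimum-duration filter. A step into or out
of a missing frame contributes zero distance and is counted. The Sidak
formula is clamped so adjusted ≥ raw holds exactly in floating point. The
relative precision of the habituation-decay estimate scales inversely with
`lambda`: at the default session noise the wild-type rate (0.08/bin) is
recovered with ~6% median error, while the mutant's shallow 0.03/bin decay
carries proportionally wider relative error.

# Problem sizes

The shipped tests run the full study at its native size — a 12 + 15 animal
cohort with one-hour open-field sessions at 30 Hz — and verify detector
exactness on 100-to-500-trial batches, protocol semantics on 1000 random
event sequences plus every 3-event sequence, bout segmentation against a
brute-force oracle on 1000 random streams, type-I error calibration on
1000 null ANOVA simulations, and byte-identical reproduction of a two-sex
end-to-end study; the whole suite completes in a few minutes on one CPU.

```{r example, eval = FALSE}
study <- run_study(seed = 1, out_dir = "study_out")
study$open_field$anova
study$pipaw$fit
```
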
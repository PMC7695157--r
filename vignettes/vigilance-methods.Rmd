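---
title: "Vigilance staging and arousal stability: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vigilance staging and arousal stability: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vigistate)
```

## The problem

During eyes-closed rest, brain arousal does not sit still: most people drift
from activated wakefulness through relaxed alpha-dominated states into
drowsiness and, sometimes, sleep onset within twenty minutes. The *speed and
depth* of this decline is a regulated trait of interest in insomnia and
affective disorders, where *hyperstable* arousal regulation — remaining in
high vigilance stages throughout — is a candidate marker of central nervous
hyperarousal. `vigistate` implements the full analysis chain for this
paradigm: stage classification of 1-s EEG epochs, stage-course summary
scores, prototype regulation typing, and the cohort statistics used to
compare patient and control groups.

## The vigilance ladder

Each non-artifact second is assigned one of seven stages, mapped to fixed
numeric scores:

| stage | score | phenomenology |
|-------|-------|----------------|
| 0     | 7     | activated wakefulness: low-voltage, no alpha, no slow eye movements |
| A1    | 6     | relaxed wakefulness, occipitally dominant alpha |
| A2    | 5     | alpha shifted anteriorly, reduced amplitude |
| A3    | 4     | strongly frontalized, low-amplitude alpha |
| B1    | 3     | low-voltage non-alpha EEG with slow horizontal eye movements |
| B2/3  | 2     | drowsiness dominated by theta/delta activity |
| C     | 1     | sleep onset: sleep spindles or K-complexes |

A2 and A3 are classified separately (their scores differ) but reported
merged as "A2/3" in amount tables.

## The classifier

The decision ladder in `classify_epoch()` is, in order:

1. an epoch overlapping a spindle/K-complex **marker** is stage C — stage C
   is bound to markers (canonically set by a human scorer; the
   `detect_events()` template detector is provided for synthetic data only
   and is explicitly non-canonical);
2. slow-wave (2–7 Hz) power at or above the slow-wave threshold, with alpha
   below the alpha threshold, gives B2/3;
3. alpha power (the larger of the anterior and posterior ROI means) at or
   above the alpha threshold enters the A branch; the anterior/posterior
   ratio r subdivides it at the cut-points `r1 = 0.5` and `r2 = 1.0`
   (A1: r < 0.5, A2: 0.5 ≤ r < 1, A3: r ≥ 1);
4. otherwise a positive slow-eye-movement detection gives B1;
5. otherwise stage 0.

Design notes, where the published description is qualitative:

* **Scalp ROIs instead of source space.** The reference implementation of
  this staging computes band powers in source space. This package uses
  scalp ROI means (anterior: Fp1/Fp2/F7/F3/Fz/F4/F8; posterior:
  P3/Pz/P4/O1/O2; global: all EEG channels), which preserves the
  anterior/posterior contrast that carries the frontalization evidence
  without a source model. For the same reason no 19-to-25-channel
  interpolation is performed: interpolated channels add no information to
  an ROI mean. Both are deliberate deviations from the published pipeline.
* **Frontalization cut-points.** Frontalization is described verbally
  ("alpha shifts anteriorly, amplitude decreases"). The ratio cut-points
  0.5 and 1.0 are configuration defaults; the amplitude-decrease clause is
  absorbed into the ratio, because anterior alpha is weaker in absolute
  terms, so an anterior-dominant ratio already implies reduced posterior
  amplitude.
* **Slow-wave band 2–7 Hz.** "Theta and/or delta" is implemented as
  2–7 Hz, cutting below 2 Hz to stay clear of the 0.5 Hz high-pass
  roll-off.
* **Precedence of rule 2 over rule 3.** An epoch with dominant slow waves
  *and* surviving supra-threshold alpha is classified into the A branch
  (rule 2 requires alpha below threshold). How the original algorithm
  resolves this is not documented; this choice is conservative toward the
  A branch and is a flagged sensitivity point.
* **One-tailed tests and tie conventions** are documented with the
  statistics functions below.

### Calibration

Alpha varies by an order of magnitude between subjects, so absolute
thresholds are anchored per subject: `calibrate()` takes an eyes-closed
segment (≥ 10 s; in practice the closed-eyes phase of an alpha-assessment
maneuver), computes the median per-epoch posterior alpha power, and sets
`alpha_threshold = 0.25 ×` that reference and `slowwave_threshold = 1.0 ×`
it. The fractions are configuration parameters — the published algorithm's
threshold constants are not public, so these defaults were fixed once
against the synthetic generator such that all planted stages separate
cleanly (see below). Subjects whose reference falls below an absolute floor
(default 10 µV²) are flagged `low_voltage_flag`; alpha-based staging is not
applicable to them and `classifier_config()` refuses such profiles, mirroring
the exclusion of low-voltage EEG subjects in practice.

### Preprocessing

`filter_recording()` applies zero-phase Butterworth filters to the EEG
channels: high pass 0.5 Hz (order 2), low pass 70 Hz (order 4), and a
4-Hz-wide band-stop notch at 50 Hz (order 2), chosen to attenuate a 50 Hz
tone by more than 20 dB while passing 10 Hz within 1 dB. The EOG pair is
deliberately left unfiltered: slow eye movements live below 0.5 Hz and
would be almost entirely removed by the high pass, so the SEM detector
applies its own 0.05–1 Hz band-pass instead. Artifact screening replaces
visual screening plus ICA correction (out of scope here) with a
deterministic per-epoch rule: any EEG channel exceeding 200 µV peak-to-peak
flags the epoch; flags are sticky and flagged epochs carry no stage.

## Summary metrics

For each recording minute and in total, `stage_amounts()` reports the
percentage of each stage group among *non-artifact* seconds
(`count × 100 / non-artifact seconds`; windows without non-artifact seconds
are missing, not zero), and `mean_vigilance_value()` averages the numeric
scores (an all-0 recording gives MVV 7, an all-C recording MVV 1).

### Arousal stability score

`minute_criteria()` evaluates each 1-min block (inclusive boundaries,
integer arithmetic, non-artifact denominators):

* I: ≥ 2/3 of seconds in 0/A stages (variant: in 0/A1),
* II: ≥ 1/3 in B stages (B1 + B2/3),
* III: ≥ 1/3 in B2/3,
* IV: at least one C second.

The recording is divided into four consecutive equal quartiles of minutes
(5 min each for the canonical 20-min recording). With qII/qIII/qIV the
earliest quartile in which criterion II/III/IV is met, the score is: qIV if
a C stage occurred (1–4); else 4 + qIII (5–8); else 8 + qII (9–12); else 14
when every evaluable minute holds the 0/A1 form of criterion I, or 13 when
only the 0/A form holds throughout. Only the four anchor values of this
table (14, 13, and 4/1 for C stages reached in the last/first quartile) are
printed in the literature; the interior bands follow forced by the
"increasingly lower scores" rule and the severity ordering II < III < IV.
The band offsets are exposed as a `score_table` argument so an alternative
official table could be swapped in. Two further conventions the source
material is silent on: blocks with fewer than 20 evaluable seconds are
skipped, and a recording stays scorable only while every quartile retains
at least one evaluable minute; when several criteria first appear in the
same quartile, the deepest criterion wins. The score is provably monotone
under "deepening" perturbations (lowering any second's stage, or moving the
first C second earlier, can never raise it), and the test suite checks this
exhaustively over single-minute modifications.

## Prototype regulation types

Individual per-minute MVV courses are assigned to prototype time courses by
the smallest sum of squared deviations (`assign_prototype()`, missing
minutes excluded pairwise, ties broken toward the more stable prototype).
The published prototype curves are verbal; the numeric defaults here are
hyperstable: constant 6 (A1 level); stable: constant 5; adaptive: linear
6 → 2 across the recording; unstable: 6 → 2 within the first quartile, then
flat. The three-prototype model merges stable and hyperstable into one
constant-6 curve. All curves are parameters of `build_prototypes()`, so
alternative shape families (e.g. exponential decline) can be substituted.

## Statistics layer

* `mann_whitney_u()`: midrank ties; exact p by full enumeration of group
  assignments for total n ≤ 16 (valid with ties), otherwise a normal
  approximation with tie and continuity correction. A standardised z is
  always reported as the effect measure. One-sided variants serve directed
  hypotheses (e.g. "patients score higher").
* `spearman_test()`: midranks; exact permutation p for n ≤ 9, else the t
  approximation.
* `chi_square_independence()`: Pearson statistic without continuity
  correction; for a directed hypothesis the one-tailed p is half the
  upper-tail probability (this halving convention reproduces published
  one-tailed chi-square values in this literature).
* `median_split()`: threshold at the sample median; values equal to the
  median are alternated into whichever half is smaller, so even-n cohorts
  split evenly even with ties at the median.
* Plain two-sample comparisons of event counts use `stats::t.test()`.

Exact p-values are verified in the test suite against brute-force
permutation oracles written independently of the implementation.

## The synthetic-data generator

No recordings are distributed with this package; the generator provides
ground-truth data with the statistical structure the analysis assumes.

**Stage courses** (`simulate_stage_course()`) follow a minute-level Markov
chain on the 7-stage ladder, expanded to seconds with changeover delays
(0–20 s) and one-level dwell excursions (p = 0.08 per second) that never
create B2/3 or C seconds outside chain minutes. Four parameter sets realize
the verbal regulation types: hyperstable courses are confined to 0/A1
(score floor 6), stable courses to the A band (floor 4, hovering near A2/A3
with low transition variance), adaptive courses descend one level per
minute with probability 0.35 down to B2/3 and may enter C (0.25 per minute
from B2/3), and unstable courses descend two levels per minute with
probability 0.92 — which makes them reach B stages within the first
quartile with probability > 0.99 and C frequently in the first half. C
minutes are rendered as B2/3 background with 1–2 embedded C seconds, since
sleep-onset events are second-scale phenomena. The exact transition matrix
is exposed (`build_stage_chain()`), so first-passage probabilities can be
computed by enumeration and compared with simulated frequencies — one of
the acceptance properties. The chain parameters are internal calibration
choices (the literature gives no quantitative per-type trajectory
statistics): they were fixed once so that realized courses match their
verbal prototype and the four types remain statistically distinguishable,
and the test suite then *measures* (rather than assumes) group separation
and ≥ 80% prototype recovery.

**Signals** (`simulate_recording()`) are sums of interpretable components:
per-channel white + low-passed noise background; narrowband ~10 Hz alpha
(random per-channel carrier frequency, common lognormal per-second
waxing/waning envelope) gated by stage and region, with relative
anterior/posterior power (0.15, 1.0) for A1, (0.6, 0.85) for A2 and
(0.5, 0.23) for A3 — i.e. ratios 0.15 / 0.71 / 2.2 against classifier
cut-points 0.5 and 1.0; global 2–7 Hz noise at 1.8 × the alpha reference
power in B2/3 and C seconds; 13.5 Hz Hann-windowed spindles (0.5–1 s) or
biphasic K-complexes on C seconds with a marker emitted per event; and
anti-phase 0.2–0.4 Hz sine half-waves of 50–150 µV on the EOG pair across
B1 runs. Amplitudes are deliberately placed far from the decision
thresholds relative to their sampling noise (ROI averaging over 5–7
channels leaves the per-epoch log band-power ratio with a standard
deviation well below the log-distance to the cut-points), which is what
makes ≥ 95% per-stage separation achievable by construction; the measured
per-stage recalls on 20 simulated recordings are part of the acceptance
suite. What the generator does **not** emulate: volume-conduction
correlations between channels, ocular/cardiac/muscle artifacts beyond
SEMs, nonstationary alpha slowing with drowsiness, or realistic inter-subject
topography differences — so passing recall tests demonstrate correctness of
the decision logic under the stated spectral model, not expected field
performance on real EEG.

**Cohorts** (`simulate_cohort()`) draw a regulation type per subject from
group-specific mixtures (defaults: patients 0.20/0.10/0.40/0.30 and
controls 0.55/0.25/0.15/0.05 over adaptive/unstable/stable/hyperstable,
i.e. a stable/hyperstable-enriched patient group), simulate the course,
compute the realized ASS, and generate covariates from a linear model on
that ASS (`covariate_model()`): sleep efficiency 97 − 2.3 × ASS (SD 10),
arousal index 6 + 0.75 × ASS (SD 4), plus group-shifted but ASS-independent
psychometric scales. The coefficient signs encode the hypothesis being
emulated — subjects with more stable daytime arousal slept worse — while
zero ASS slopes on the psychometric scales emulate the reported absence of
such correlations. All randomness derives from one cohort seed through a
documented splitting scheme (`split_seed()`), so whole cohorts are
bit-reproducible.

## Numerical choices and problem sizes

Band powers come from Hann-windowed periodograms on 1-s epochs (1 Hz
resolution; band edges inclusive), normalised so the one-sided sum
approximates the epoch variance. The SEM detector evaluates a 4-s window
centred on each epoch (sub-0.5 Hz energy cannot be resolved within 1 s).
Zero-phase filtering is used throughout, so no group delay correction is
needed; filtering is idempotent for in-band content within 2%. Scoring
ties: all criterion comparisons are done in integer arithmetic
(`3 × count ≥ n`), so 20 of 60 seconds meets a 1/3 boundary exactly.

The test and acceptance suites run at deliberately modest problem sizes
chosen as representative rather than exhaustive: 2000 simulated courses for
the first-passage comparison (±3% tolerance against enumeration), 200
replicate cohorts of 34 + 25 subjects for the group-separation and
prototype-recovery properties, 200 random configurations for the
exact-test/brute-force equivalence, and 20 seven-minute recordings (one
minute per stage) for classifier recall.

## Known limitations

* Scalp-ROI staging is not the published source-space algorithm; agreement
  with it on real data is untested and bit-level replication is a non-goal.
* The interior ASS bands (5–12) are a documented reconstruction, not a
  published table.
* The official numeric prototype curves are unavailable; distribution
  comparisons on real cohorts should treat curve shapes as a sensitivity
  parameter.
* Stage C depends entirely on supplied markers; without markers, deep
  drowsiness with spindles will be scored B2/3.
* Absolute-amplitude parameters (artifact limit, SEM amplitude floor,
  low-voltage floor) assume microvolt-scaled input; rescaled data require
  rescaled limits, as exercised in the self-consistency test.
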
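---
title: "Assessing upper-limb reaching with armkin: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing upper-limb reaching with armkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assessment task and its parameters

`armkin` analyses a planar "horizontal catch" reaching exercise performed in
a gravity-support arm exoskeleton. A trial presents up to 12 targets
sequentially in a 40 x 30 cm horizontal workspace; the subject has 10 s to
catch each ball, a trial lasts at most 120 s, and the protocol repeats 10
trials per session over 3 sessions on consecutive half-days. The device
records hand position in the plane at 64 Hz together with timestamped
target events.

The atomic unit of analysis is the **unitary movement**: the trajectory
between two *consecutively caught* targets. A movement is discarded when
either endpoint timed out, and the approach to target 1 never counts
because subjects often start with the hand already on the first ball — so
a complete trial contributes at most 11 movements. From each trial the
package computes:

* **TaskTime** (s): first target appearance to last target resolution
  (capped at 120 s); global temporal efficiency.
* **MovementTime** (s): time between consecutive catch events, averaged
  over valid movements.
* **PeakVel** (cm/s): maximum planar speed per movement, averaged.
* **HPR**: traveled path length over straight-line distance between the
  catch positions (>= 1); spatial efficiency.
* **nPeak**: number of positive-to-negative sign changes of the speed
  derivative; movement smoothness (fewer = smoother).
* **Score** (%): caught / presented targets.
* **PercPeakVel** (%): time of the speed maximum as a fraction of the
  movement duration; a right shift indicates a longer corrective phase.

## Differentiation and smoothing

Positions are differentiated with central finite differences and the planar
speed magnitude is low-pass filtered with a 2nd-order zero-phase
Butterworth filter, default cutoff 6 Hz (`kin_config()`). The cutoff is a
deliberate, documented default: counting derivative sign changes on raw
64 Hz differences is dominated by sensor noise, and an undocumented filter
would make nPeak irreproducible. Zero-phase filtering preserves the timing
of the peak (PercPeakVel). At 64 Hz the filter attenuates the peak of a
1 s minimum-jerk speed bell by well under 0.1%, so PeakVel keeps its
closed-form anchor 1.875 D/T. Segments shorter than 15 samples are left
unfiltered (zero-phase filtering needs padding); the profile records the
smoothing actually applied. Filtered speed is clamped at zero and runs of
zero derivative are compressed before peak counting, so a flat-topped
maximum counts once. Ties for the global maximum resolve to the earliest
sample. Movements displaced less than 0.5 cm are degenerate (HPR
undefined) and are dropped from movement-level averages.

## Outlier screening and aggregation

Per-trial parameter values are screened with Tukey fences
(Q1 − 1.5 IQR, Q3 + 1.5 IQR). Quartiles default to Tukey's hinges
(`stats::fivenum()`), the estimator of the original boxplot rule; a
type-7 quantile option is provided because quantile conventions move the
fences. The screen is applied per parameter across all subject x session x
trial values by default (a per-session scope is available); the level at
which the original analysis applied its screen is not documented, so the
default is stated prominently rather than silently assumed. Flagged cells
become explicit missings — the table never loses rows. Session-level
values are means over a stated trial subset; cells with no available
trial stay missing and are reported (a subject who stops after 6 trials
has no last-4-trials mean).

## Learning and retention statistics

Learning is tested with a two-way fully-within repeated-measures ANOVA
(10 trials x 3 sessions) on complete-case subjects. Each within effect is
tested against its own subject-by-effect interaction mean square.
Sphericity is assessed per effect with Mauchly's test on the
orthonormal-contrast covariance (with the second-order Box term of the
standard R implementations); when rejected at 0.05 the
Greenhouse-Geisser epsilon — `tr(S)^2 / (d tr(S^2))` clipped to
`[1/d, 1]` — shrinks both degrees of freedom of the F test. The policy is
configurable (`"mauchly"`, `"always"`, `"never"`) because applying the
correction only after a significant Mauchly test is itself a modelling
choice. Significant omnibus effects are followed by Tukey HSD contrasts
using the same error term (degrees of freedom epsilon-shrunk when the
omnibus was corrected); trial contrasts are pooled across sessions when
the interaction is not significant, i.e. the same trial effect is assumed
in every session.

**Retention** is a verdict about the last two sessions: gains are retained
when S2 vs S3 is non-significant while S1 may differ from later sessions.
A parameter with no session effect at all is vacuously retained — there
was no learning to lose.

The implementation of the partition, Mauchly's W, epsilon and the
post-hocs is authored in the package (it is the method under study) and is
cross-checked in the test suite against `stats::aov` error strata and
`car::Anova`'s repeated-measures corrections on random designs.

## Test-retest reliability

Reliability uses the session means of the last four trials of sessions 2
and 3 — the window where learning has plateaued. From the subjects x
sessions ANOVA mean squares (MSR, MSC, MSE):

* **ICC(2,k)** — two-way random effects, absolute agreement, average
  measures: `(MSR − MSE) / (MSR + (MSC − MSE)/n)`. Confidence bounds use
  the F-based interval of the single-measure ICC(A,1) with the
  Satterthwaite denominator degrees of freedom, stepped up with
  Spearman-Brown. Classification: excellent >= 0.75, moderate 0.40-0.75,
  weak < 0.40.
* **SEM** = sqrt(session variance component + residual MS), with the
  session component `(MSC − MSE)/n` truncated at zero when its estimate is
  negative (standard ANOVA-estimator practice; occurrences are logged).
  Including the session component is deliberate: systematic test-retest
  bias (residual learning) is part of the measurement error a clinician
  competes against. The phrase "variance of individual differences between
  test and retest" admits a second reading — the within-subject mean
  square — so that diagnostic is emitted alongside as `sem_wms`.
* **MDC95** = 1.96 x SEM x sqrt(2), and **MDC%** = 100 x MDC95 / grand
  mean, where the grand mean averages all observations across both
  sessions (equal to the mean of the two session means only under
  balance).
* The **mean difference** retest − test is reported with a normal-quantile
  CI by default (a t-quantile option exists); the published example
  half-widths are consistent with the 1.96 multiplier, and the paper-trail
  of which multiplier was originally used is not recoverable. A CI
  excluding zero flags residual systematic bias.

`reliability_vs_trials_sweep()` recomputes ICC and MDC for the last
k = 1..10 trials, tracing how much within-session averaging the protocol
needs before reliability stabilizes.

## The synthetic cohort generator

No patient-level recordings are publicly deposited for this protocol, so
the generator produces raw trial logs with the statistical structure the
analysis assumes, giving every downstream estimator a known ground truth.

**Trajectories.** Each reach is a superposition of equal minimum-jerk
displacement lobes along a circular arc whose arc/chord ratio is the
curvature parameter; with rests between lobes each contributes one
velocity peak, and the noiseless HPR equals the curvature. A subject's
latent **ability** in [0, 1] maps to peak speed, pre-movement dwell,
submovement tendency, curvature and spatial accuracy.

**Failures.** A target fails either because the reach is too slow (dwell +
movement exceeds 10 s; the hand is caught mid-reach) or because it misses
spatially and hovers off-target until the timeout. The miss channel is
essential: failure probability and movement duration would otherwise be
locked together, whereas observed cohorts combine a Score SD near 37
percentage points with a MovementTime SD under 1 s — successful reaches
stay fast even in subjects who fail often.

**Learning.** A gain state approaches 1 exponentially over cumulative
trials and is multiplied by a retention fraction (default 1 = perfect
retention) at each session boundary, because the observed learning curves
show fast early improvement, a plateau, and no loss across days. The
default rate (0.35 per trial) makes learning essentially complete within
session 1: the generator's defining phenomenology is "learning mainly
between session 1 and sessions 2/3, then retention", and a slower rate
would leave the gain still climbing through session 2, creating a genuine
S2-S3 difference that contradicts the retention pattern the cohort is
supposed to embody. The gain reduces dwell, submovement count and
curvature. Peak speed deliberately carries **no** learning component, and
movement duration is derived from it (T = 1.875 L / v), reproducing the
empirical pattern that MovementTime improves while PeakVel does not.
Per-(subject, session) day effects implement the session-bias variance
component; without them the subject x session error term would be
unrealistically small and any residual S2-S3 drift would reach
significance, destroying the retention signature at n = 30. The day
effects share a common day-quality factor across channels (share 0.9):
fatigue, motivation and spasticity fluctuate per day and move speed,
pauses, smoothness and path quality together, so a subject's "bad day"
degrades all parameters at once rather than each independently. Pause,
curvature and submovement day effects are multiplicative (proportional to
the subject's own scale); the peak-speed day effect is additive (cm/s) so
that day-to-day speed variability is homoscedastic across the ability
range — a multiplicative effect would let the fastest subjects dominate
the subject x session error term and distort the size of the (truly null)
PeakVel session test.

**Noise.** Hand unsteadiness is modeled as smooth low-frequency postural
wobble (two random sinusoids per axis, 0.5-2 Hz, ~0.06 cm, continuous
across the trial so block boundaries cannot create velocity spikes). White
measurement noise defaults to zero: the number of ripple maxima of
low-pass-filtered white noise does not shrink with its amplitude, so any
white floor would dominate the peak count during pauses — a behaviour real
recordings do not show.

**Calibration.** The default constants were calibrated once against the
published session-2/3 scale of the task and then frozen: with the default
spec a 30-subject cohort lands near MovementTime 3.5/3.6 s, PeakVel
28/29 cm/s, Score 75/74%, TaskTime 56/56 s, HPR 1.79/1.80 and nPeak
6.3/6.3 for sessions 2/3 — within 15% of the published means, with one
systematic exception: because the generator embodies *perfect* retention
its session-3 values do not decline below session 2, whereas the published
cohort still improved slightly between those sessions (its MovementTime
fell to 2.97 s), so the generator's session-3 MovementTime sits about 20%
above that cell. Matching both the residual session-2-to-3 decline and a
non-significant session-2-vs-3 contrast in nearly every replicate is not
possible simultaneously; the retention phenomenology won. The generator
also compresses some between-subject SDs (MovementTime, nPeak, Score
spreads are 25-50% smaller than published) and its day-to-day variance
components are milder, so its ICCs sit mostly in the excellent range and
its MDC% values are lower than the published 43-110%. Passing tests on
this cohort therefore demonstrate that the estimators recover what the
generator put in and that the qualitative learning/retention signature
(session effects for TaskTime/MovementTime/HPR/nPeak, none for PeakVel,
non-significant S2-S3 contrasts) is reproduced — they do not certify the
full covariance structure of real patient data.

## Validation problem sizes

The test suite validates the ANOVA partition against brute-force
decomposition and reference implementations on random small designs; the
GG-policed session test holds its nominal size within [3%, 7%] over 500
null cohorts of n = 30; ICC and SEM recover known variance components
within ±0.05 and ±10% over 50 cohorts of n = 200; and the end-to-end
signature is required in at least 90% of 50 full 30-subject trajectory
cohorts. These sizes were chosen to bound Monte-Carlo error well below
the tolerances they guard.

## Known limitations

* Unbalanced repeated-measures designs are handled by complete-case
  reduction, not by mixed models; subjects with missing cells are excluded
  from the ANOVA (and counted), mirroring the original analysis choice.
* The trial-log dialect is a documented stand-in; the vendor's raw format
  is proprietary and unpublished.
* The generator's ability model is one-dimensional; real impairment
  profiles dissociate speed, accuracy and smoothness more than a single
  latent scalar allows, which is the main reason some between-subject
  SDs come out compressed.
* PercPeakVel is measured over the full catch-to-catch segment (including
  the pre-movement dwell), which shifts it rightward relative to analyses
  that window the ballistic phase only.
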
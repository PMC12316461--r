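---
title: "Models and design choices in sociodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in sociodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sociodyn)
```

sociodyn packages four analysis chains used in studies of rodent social
behavior and its neural correlates, together with generators that synthesize
each input class with planted ground truth. This vignette explains the
models, the parameters that matter, and the design choices made where the
underlying procedures leave room for interpretation. Every empirical claim
here is one the package's test suite or `scripts/acceptance.R` computes.

## First-order Markov analysis of behavior sequences

A behavior sequence is one categorical label per 1-s bin. `fit_transitions()`
counts transitions between consecutive bins — including self-transitions,
because per-bin labels make dwelling in a behavior a transition from the
state to itself, and the "within-state" probabilities of the two-state model
would otherwise be undefined — and row-normalizes by each state's outgoing
transitions. The final bin has no outgoing transition, so a state's
normalizer is its outgoing count, not its raw occurrence count.

Two statistics probe the fitted chain.

**Order.** `g_order_test()` computes
$G = 2\sum_j\sum_i O_{ij}\,\ln(O_{ij}/E_{ij})$ against the zeroth-order
(memoryless) null. The null's expected counts use the standard
independence-table form $E_{ij} = n_{i\cdot} n_{\cdot j}/N$ — the product of
observed margins — since "no time dependence" pins down the null only up to
its margins. Conventions: $0\ln 0 = 0$; cells with $E_{ij}=0$ (unoccupied
margins) are excluded; degrees of freedom are $(k-1)^2$ with $k$ the number
of states that actually occur. On the alternating sequence ABABABA this
gives $G = 12\ln 2 \approx 8.318$ on 1 df, checkable by hand.

**Stationarity.** `lrx_stationarity_test()` splits the sequence into
segments of near-equal duration (earlier segments absorb remainder bins) and
computes $LRX = 2\sum_s\sum_j\sum_i f_{ijs}\,\ln(\bar p_{ijs}/p_{ij})$. The
reference $p_{ij}$ is estimated from the *pooled per-segment counts* rather
than from the uninterrupted full sequence. The two differ only by the
transitions spanning segment boundaries, but the pooled form is the one with
the right likelihood-ratio structure: it makes $LRX$ exactly zero whenever
all segments share the same transition counts, guarantees $LRX \ge 0$
(Gibbs' inequality), and matches the classical contingency-table test of
homogeneity across segments. Degrees of freedom are $(S-1)\,k\,(k-1)$.

Both tests are calibrated: on 500 memoryless (respectively stationary)
sequences of $10^4$ bins, rejection rates at $\alpha = 0.05$ land within
$0.05 \pm 0.02$ (the acceptance script recomputes these).

**Multi-label bins.** Manual annotation sometimes assigns several codes to
one second. `resolve_multilabel()` resolves each bin by category priority,
social over nonsocial by default — when the question is social engagement,
a second containing any social behavior is a social second. The priority
list is an argument, so the opposite convention is one keystroke away.

## Pose-geometry interaction detection

`detect_interaction()` marks a frame as a cup interaction when (a) the nose
keypoint lies within 1.3× the cup diameter of the cup and (b) the cup center
falls inside a 90° cone (half-angle 45°) in front of the head. Choices the
geometric rule leaves open, and their defaults:

* *Distance reference.* Nose to cup **center** (`distance_to = "center"`),
  the simplest consistent reading; `"edge"` subtracts the cup radius.
* *Head direction.* The neck→head vector, falling back to head→nose when
  the neck keypoint is missing; frames where both pairs are degenerate
  (coincident points) count as not interacting and are tallied in an
  `n_undefined` attribute rather than erroring.
* *Cone width.* "90°" is read as the full apex angle, so the test is
  against a 45° half-angle.

Detections are aggregated into 40-ms bins (`binarize_bins()`); a bin is
positive when *any* overlapping frame is positive (a majority rule is
available). Note a subtlety of mismatched time bases: at 20 fps each 50-ms
frame overlaps one or two 40-ms bins, and some bins overlap only a single
frame, so bin patterns are not a simple 2-frames-per-bin decimation — that
ratio would require 50 fps.

`extract_trials()` turns the bin vector into discrete trials by applying, in
order: merge pauses shorter than 1.5 s; discard candidates shorter than 1 s;
discard candidates starting less than 5 s after the end of the previous
*accepted* trial. Merging first is deliberate — a bout interrupted by a
sub-1.5-s pause is one interaction, and its merged duration is what the
1-s minimum should see. The refractory reference is the last accepted
trial, so a rejected bout does not reset the clock.

## auROC response classification

`roc_auroc()` sweeps 100 linearly spaced thresholds from the minimum to the
maximum of the z-scored trace (both endpoints included; a bin is "active"
when $z \ge$ threshold, so ties at a threshold count as active). Each
threshold yields TPR/FPR against the behavior vector; the curve is sorted by
FPR, anchored at (0,0) and (1,1), and integrated trapezoidally. On instances
whose values the 100-step grid can resolve, the result agrees with the
exhaustive pairwise (Mann–Whitney) oracle to within 0.02 — the grid's
discretization tolerance — and satisfies auROC(−z) ≈ 1 − auROC(z) to the
same tolerance.

The null (`circular_shift_null()`) circularly rotates the behavior vector by
a uniform random offset in $\{1,\dots,T-1\}$ — never 0, so no null draw
reproduces the observed alignment — and recomputes auROC; 1000 draws by
default, offsets sampled with replacement. Rotation preserves the behavior
vector's autocorrelation while destroying its alignment with the trace,
which is what makes the null fair for slow, blocky behavior vectors.
`classify_response()` calls a cell excited when its auROC *strictly
exceeds* the null's 97.5th percentile and inhibited below the 2.5th;
percentiles use R's default linear-interpolation convention (type 7). The
resulting two-tailed type-I error on pure-noise cells is 5% ± 2% (computed
over 500 cells in the acceptance script).

Because calcium frames (50 ms at 20 fps) and behavior bins (40 ms) live on
different time bases, `align_to_bins()` assigns each bin the nearest frame's
z value by default; linear interpolation is available. Nearest-frame
assignment duplicates some frames, which is harmless for the permutation
test because the null sees the same duplication pattern as the observed
statistic.

Peri-event averaging (`event_triggered_average()`) uses trials from
`extract_trials()` — not raw bins — in a ±5 s window, excluding (and
counting) trials truncated by session edges. `cluster_response_profiles()`
concatenates each cell's social and object averages into one row, clusters
with Ward's method on Euclidean distance, and cuts the tree at 0.770× the
maximum linkage height. `stats::hclust(method = "ward.D2")` is the variant
that matches Ward's criterion on raw (unsquared) Euclidean distances, i.e.
the same tree SciPy's `linkage(..., "ward")` produces.

## Intrinsic electrophysiology

The step protocol is 1-s current steps from −120 to +260 pA in 20 pA
increments (10 kHz sampling in the synthetic recordings, with 0.25 s of
baseline on each side of the step). Feature definitions and the choices
behind them:

* **Sag** (−120 pA step): steady-state minus peak. "Steady state" is the
  mean over the final 200 ms of the step; the peak is the minimum after a
  2-ms boxcar. The smoothing matters: the raw minimum of a noisy sweep is
  biased downward by the extreme-value statistics of the noise (about
  3.7 SD for $10^4$ Gaussian samples), which would inflate every sag
  estimate by ~0.7 mV at 0.2 mV noise.
* **Ramp ratio**: mean deflection 900–1000 ms after onset divided by the
  mean 100–200 ms after onset, on the largest depolarizing step with no
  detected spikes. Deflections are measured from the pre-step baseline so
  the ratio never divides by a near-zero absolute potential.
* **Firing delay**: latency from onset to the first spike on the rheobase
  step (the lowest-current step with any spike). Spikes are upward
  crossings of 0 mV with a 2-ms refractory period; the threshold is a
  parameter since the underlying criterion is rarely stated.
* **Max instantaneous frequency**: max of 1/ISI over consecutive spike
  pairs falling entirely within the first 100 ms of any depolarizing step.
* **Capacitance**: from a single-exponential fit to the charging curve of
  the smallest hyperpolarizing step, $C = \tau/R$ with $R$ from the
  steady-state deflection. This is a membrane-time-constant approximation,
  not a full charge-integration method, and is labeled as such.

All four intrinsic features are invariant to a constant offset in Vm (the
spike threshold is absolute, so the invariance holds for offsets that keep
spikes crossing 0 mV).

Optogenetic sweeps (8 pulses at 30 Hz) are measured against the mean of the
5 s before light onset. The EPSP peak is searched in a fast 100-ms window
after the first pulse (5-ms boxcar); the IPSP trough over the full 5.5 s
(50-ms boxcar), reflecting slow IPSP kinetics. A PSP counts as present when
it exceeds 3× the smoothed baseline SD and an absolute floor of 0.5 mV —
both extrema of noise alone would otherwise cross any purely SD-based
threshold over a 5.5-s search window. IPSP decay tau comes from a
single-exponential least-squares fit (Levenberg–Marquardt) from the trough
to the first return to baseline, capped at 5.5 s; non-convergence yields a
missing value rather than an error. Classification: IEI firing data, when
present, takes precedence (IEI down = excitation, up = inhibition);
otherwise EPSP-only = excitation, IPSP-only = inhibition, both = mixed,
neither = none. The voltage-area sign resolves mixed cells only for
dendrogram annotation (`resolve_mixed = TRUE`), leaving the mixed class
intact elsewhere.

`cluster_baseline()` max-min normalizes each feature to [0, 1] and applies
Ward/Euclidean clustering, reporting the two top-level clusters and their
response-class composition. A constant feature would normalize to 0/0, so
it errors, naming the feature; rows with missing features are dropped and
counted. The intended feature menus differ by region: ramp ratio, max
firing frequency, firing delay and sag for central-amygdala-like data;
capacitance replacing ramp ratio for cortex-like regions where it separates
pyramidal cells from interneurons.

## What the generators emulate — and what they do not

Each generator draws from its own seeded RNG stream and restores the
caller's RNG state, so results are bit-reproducible given (spec, seed).

* `gen_markov_sequence()` starts chains from the stationary distribution
  (uniform fallback when it is not unique), eliminating burn-in bias at
  short lengths.
* `gen_pose_session()` places the nose at 0.6× the cup diameter, pointing
  at the cup, during planted bouts, and random-walks the animal with its
  nose kept beyond 1.5× the diameter of both cups otherwise; ground truth
  is defined by frame midpoints so that noiseless sessions are detected
  *exactly*. Keypoint jitter is Gaussian and independent per frame — real
  tracking errors are correlated in time and occasionally catastrophic
  (identity swaps, occlusions), which this does not model.
* `gen_calcium_population()` adds exponential-decay transients (0.5 s tau,
  GCaMP7f-like) at event onsets on Gaussian noise. Real traces have
  correlated noise, baseline drift and crosstalk; passing the calibration
  tests here shows the statistics are correct under their stated
  assumptions, not that those assumptions hold for any particular
  recording.
* `gen_ephys_cell()` synthesizes sag as a double-exponential transient
  (100 ms decay, 10 ms rise), numerically rescaled so the waveform minimum
  sits exactly the planted sag below steady state despite overlapping the
  charging curve; subthreshold ramps are linear in time with the planted
  late/early ratio; spikes are 1.5-ms triangular waveforms at planted
  times. The strongest step carries an immediate burst at the planted
  maximum instantaneous frequency. Real spike shapes, adaptation and
  stochastic firing are out of scope.
* `gen_tube_contests()` draws winners by a logistic function of the latent
  rank gap; an infinite gap is deterministic.

## Problem sizes and runtime choices

The validation suite uses sizes at which the asymptotic are already stable
but a laptop core stays comfortable: $10^4$-bin sequences and 500 replicates
for null calibrations; 500 noise cells (1000 permutations each) for the
type-I rate; 100 synthetic cells per ephys recovery run; a 12-animal,
20-cells-per-animal cohort with 240-s sessions for the end-to-end
pipeline. The threshold-sweep auROC is computed by bucketing each bin's z
value into the threshold grid once and re-tabulating per permutation, which
makes the 1000-draw null linear in the session length.

## Known limitations

Interaction geometry is 2-D; a rearing mouse can point its nose "at" a cup
it is not engaging with. The juvenile-intruder two-state analysis inherits
whatever observer bias the manual annotation carries. The capacitance
estimate is a time-constant approximation. Group-level inference (ANOVAs,
paired tests across conditions) is deliberately left to the user: the
package computes per-subject and per-cell quantities in tidy tables that
drop straight into standard R modeling functions.
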
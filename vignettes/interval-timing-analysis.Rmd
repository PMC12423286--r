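---
title: "Analysing interval-timing behavior and neural population activity with crowtime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing interval-timing behavior and neural population activity with crowtime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and the data model

`crowtime` implements an analysis pipeline for delayed-response interval-timing
experiments: on each trial a visual cue — one of two stimulus protocols
(`color`, `shape`) crossed with three target durations (1500, 3000, 6000 ms) —
instructs the subject to wait at least the cued duration after cue offset
before responding, with a response window equal in length to the target
duration. Responses from 20 % before the target time onward are scored
correct (earliest-correct times 1200 / 2400 / 4800 ms); later responses than
the window are late errors; responses after 1200 ms but before the cued
duration's own earliest-correct time are early errors; anything earlier is an
abort. Simultaneously recorded single units provide a spike table with times
in milliseconds relative to cue onset — the single time convention used
everywhere in the package, with half-open bins `[a, b)` so no spike is ever
counted twice.

All analyses consume a `session_recording`: a trial table (events, outcome,
cued duration, protocol), a spike table, and a neuron table. Real data in
this columnar form can be read with `read_session()`; synthetic sessions with
full ground truth come from `generate_session()`.

## The synthetic world

The generator states a world rather than offering dials to tune:

* **Behavior.** Reaction times are Gaussian on the wait clock with mean
  `d (1 + mean_offset_fraction)` and SD `weber_fraction × mean` — the scalar
  property (constant Weber fraction) built in by construction. Defaults:
  Weber fraction 0.2 and overshoot 0.1, matching the regime the behavioral
  fits report (fitted spread-to-center ratios near 0.2, centers ~10 % beyond
  the target); opt-out probability 0.3 on the longest duration (early aborts
  within 400 ms of the wait onset), reflecting the frequent strategic aborts
  observed on 6000 ms trials. Truncation at zero is by resampling, keeping
  the distribution unimodal.
* **Spikes.** Inhomogeneous Poisson emission by thinning from per-condition
  rate profiles. Poisson is an assumption — the data this pipeline targets do
  not constrain spike-count dispersion — and is the simplest process
  consistent with everything the analyses measure; an overdispersion knob is
  deliberately deferred.
* **Archetypes.** `rate_profile_spec()` parameterises the response motifs the
  analyses probe for: categorical duration tuning (constant gain for a
  preferred duration, switching on at cue onset when the cue reveals the
  condition), transient time fields (Gaussian bumps tiling the wait;
  ensembles form sequences), three ramp shapes reaching `baseline + gain` at
  the target time, temporally scaling templates (the profile for duration *d*
  is the reference template stretched by `d / d_ref`), protocol-bound gains,
  and untuned baselines.

One synthetic session contains all neurons simultaneously; the
pseudopopulation assembly in the decoders still redraws and re-pairs trials
per neuron per resample, mirroring analyses that pool neurons recorded across
sessions with no true simultaneity.

What a green test on this world does establish: the estimators recover the
generating parameters, the decoders are calibrated at chance under label
permutation, and structurally distinct codes (static vs dynamic, invariant vs
protocol-bound) produce their expected signatures. What it does not
establish: robustness to non-Poisson dispersion, inter-neuron noise
correlations, electrode drift, or any other feature of real recordings the
generator does not emulate.

## Behavioral quantification

`histogram_rts()` bins RTs into 200 ms intervals from zero;
`fit_rt_gaussian()` fixes the Gaussian's center at the modal bin's center
(ties broken to the earliest bin, deterministically) and fits amplitude and
sigma by least squares on the raw counts. Fixing the center stabilises the
spread estimate against early low-frequency responses; on the longest
duration the first two bins (400 ms) are excluded as opt-outs rather than
genuine estimates. The least-squares surface for sparse, jagged histograms
has a spurious zero-width local minimum (a spike on the modal bin), so the
optimiser is multi-started from a log-quadratic estimate, the weighted SD
around the fixed center, and two scale-based guesses, keeping the best fit.
`scalar_summary()` then reports sigma against center: a strictly increasing
relation is the scalar-expectancy signature.

## Single-unit statistics

Selectivity uses a two-way ANOVA (duration × protocol, α = 0.01) on per-trial
mean rates in two 1200 ms windows: cue-offset-aligned (start of the wait) and
response-onset-aligned (end of the wait). A *time neuron* has a significant
duration main effect and no protocol or interaction effect. Because the
delayed-retry protocol leaves cell counts unbalanced, Type II sums of squares
are used (each main effect adjusted for the other, no interaction assumed
when testing main effects); on balanced data this reduces to the classical
decomposition, which is what the vectorised sliding-window path
(`balanced_anova_ss()`) computes and what the tests verify against the
per-column route.

Tuning curves min–max normalise the three duration means to 0–100 %; tuning
width is the weighted SD of the durations with the normalised responses as
weights. Preferred-duration ties break to the shorter duration with an
explicit flag. Monotonicity is defined non-strictly for the extreme-duration
preferrers (a shortest-preferring neuron is monotonic iff its rates are
non-increasing with duration; symmetric for longest), and undefined (NA) for
middle preferrers. The Jonckheere–Terpstra trend test is implemented in full:
pairwise Mann–Whitney counts with ties at one half, tie-corrected normal
approximation, and exact enumeration of all `N!/∏ nᵢ!` group assignments for
pooled `n ≤ 12`.

Ramping ("increasing") classification compares the final 600 ms before the
response to the initial 600 ms after cue offset with a paired t-test
(α = 0.05), and requires the final-600 ms mean to be the profile's peak. The
peak is assessed in 600 ms windows — the same granularity as the endpoint
comparison — because a max over 100 ms bins is upward-biased by bin noise and
would veto genuine ramps. Model fits (linear, exponential `a·e^{bt} + c`,
sigmoidal `L/(1+e^{-k(t-t₀)}) + c`) run per duration on 100 ms-binned,
min–max-normalised wait profiles; the nonlinear shapes are profiled over a
parameter grid with closed-form amplitude/offset at each grid point, which
makes the 1000 bin-label shuffles of the null affordable and fully
deterministic. Significance is judged against the neuron's own 95th shuffle
percentile per model — the conservative per-cell reading of
"better than chance".

Temporal scaling compresses the longer condition's 10 ms-binned profile by
each candidate factor (linear interpolation onto the shorter condition's bin
centers — the simplest alias-free resampling at this resolution) and takes
the MSE-minimising factor. The default grid is 0.05–3.0 in steps of 0.05: a
coarser grid starting at 0.3 cannot represent optima below 0.3, which the
analysis must be able to report (a four-fold stretch has its optimum at
0.25). Exact two-fold and four-fold stretches recover 0.5 and 0.25; the
identity comparison recovers 1.0 with zero MSE. On unrelated noise profiles
the argmin is attracted to the small-factor end of the grid, where few
overlapping bins make the MSE estimate noisy — a caveat for interpreting
single-neuron optimal factors, and one reason the population-level
within-10 % fraction is the more meaningful summary.

## Decoding

All decoders share one engine: a linear SVM (L2-regularised, L1 hinge loss,
`C = 1` — the conventional default, configurable) solved by dual coordinate
descent, with one-vs-one multiclass voting, stratified cross-validation, and
z-scoring computed from training rows only (zero-variance features map to 0,
keeping silent neurons neutral). No SVM package is assumed; the solver is
part of the package and is exercised against separability, chance-
calibration, and silent-channel invariance tests.

* **Within/cross-protocol generalization** (`protocol_generalization_decode`):
  within-protocol accuracy uses 5-fold CV inside one protocol's
  pseudopopulation (15 trials per class: 12 train / 3 test); cross-protocol
  training uses all of one protocol's pseudotrials and tests on all of the
  other's — disjoint by construction, so no fold machinery crosses the
  protocol boundary.
* **Pooled duration decoding** (`duration_decode`): 30 trials per class,
  10-fold CV (27/3), confusion matrices averaged over folds and resamples,
  shuffled-label null with its 99th percentile.
* **Elapsed time** (`elapsed_time_decode`): within one duration, the first
  `0.8 d` of the wait is split into 20 bins; each (trial, bin) pair is an
  observation (400 per neuron at 20 trials), the feature being the neuron's
  min–max-normalised mean rate in that bin — the reading adopted for
  "average normalised firing rate per observation", flagged as an
  interpretation. 5-fold CV gives 320/80 splits with each bin exactly four
  times per test fold; predicted-bin distributions accumulate per true bin.
* **Correct vs late error** (`error_trial_decode`): two-class decoder trained
  on correct trials (10-fold CV) and additionally tested, with the training
  fold's scaler, on late-error pseudotrials resampled each iteration.
* **Cross-temporal matrices** (`cross_temporal_decode`,
  `bin_stability_decode`): train at one 200 ms window (20 ms steps) or one
  proportional wait bin, test at every other, applying the training window's
  scaler to all test windows. Square patterns indicate static codes,
  diagonal ridges dynamic codes.
* **Cluster permutation test** (`cluster_permutation_test`): pixelwise
  thresholds at the 99th null percentile, candidate clusters by
  4-connectivity (the stricter standard adjacency, since the convention is
  otherwise unstated), and cluster significance by rank against the null
  maximum-cluster-size distribution.

Pseudotrial pairing across neurons is uniform random without replacement per
resample; all resampling is driven by a single seed per analysis.

## Population dynamics

The percent-explained-variance time course applies the sliding-window ANOVA
per neuron and converts each factor's sum of squares to the bias-corrected
effect size

ω² = (SS_term − df·MS_error) / (SS_total + MS_error) × 100,

averaged across neurons, resampled 20× with fresh balanced trial draws
(15 per duration × protocol cell), with a baseline from 50 label shuffles per
resample (1000 reshuffles total). ω² is deliberately not floored at zero:
small negative values under the null are the bias correction at work, and the
baseline panel makes that visible rather than hiding it.

State-space trajectories condition-average each neuron (20 ms bins, 200 ms
Gaussian smoothing with edge renormalisation), z-score neuron-wise over the
concatenation of all three durations, and fit a single PCA on that
concatenation: a common basis is what makes between-condition Euclidean
distances meaningful, so per-condition PCAs are not offered. Per-duration
windows run from 900 ms before cue onset to the earliest-correct time
(2700 / 3900 / 6300 ms spans, derived from the event times). Component signs
are fixed by making each component's largest-magnitude loading positive, so
plots reproduce across platforms. Amplitude is the distance of each state
from the cue-onset state (zero at the reference by construction); velocity is
the distance between consecutive states per second, displayed after 5-bin
boxcar smoothing.

## Numerical and design notes

* Windows are half-open everywhere; a spike exactly at a window end belongs
  to the next bin.
* Gaussian smoothing renormalises the kernel to its in-window mass, so
  constants are preserved and short windows show no edge droop.
* The 0.5 Hz inclusion rate is computed on correct trials only (consistent
  with every other analysis being restricted to correct trials unless stated
  otherwise); both inclusion boundaries are inclusive.
* Ramp fits run per duration on cue-offset-aligned activity; which alignment
  (or concatenation) the original analyses used is not determinable, so the
  choice is explicit and configurable.
* Sessions at desk scale use tens of trials per cue and tens of neurons;
  the full-study resample counts (1000) are the function defaults, and the
  analysis drivers state where they scale them down.

## Known limitations

No renewal or negative-binomial spike processes, no inter-neuron noise
correlations beyond shared rate profiles, no LFP, no spike sorting or
waveform QC (inputs are assumed sorted), no nonlinear decoders, no demixed
PCA or nonlinear embeddings; amplitude and velocity are descriptive
geometry, not inferential statistics.
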
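---
title: "Methods: transition-triggered calcium analysis of courtship song"
author: "songCalcium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transition-triggered calcium analysis of courtship song}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songCalcium)
```

## The analysis problem

Male *Drosophila* alternate between pulse and sine song on a timescale of
a few hundred milliseconds, while calcium indicators report neural
activity through kinetics that are slow (seconds) and asymmetric (fast
rise, slow decay). Comparing raw ΔF/F levels *during* each song mode is
therefore confounded: sustained activity accumulates indicator signal, and
whichever mode tends to occur later in a stimulation epoch inherits an
inflated baseline. The package's central design, following standard
practice in the field, is to quantify selectivity from the *changes* in
ΔF/F around song-type transitions instead: a short pre/post contrast is
far less sensitive to slow temporal summation than a state-wise mean.

Everything in the package serves that comparison: song labels on a 1.6-ms
classifier grid are cleaned and reduced to the imaging frame grid; typed
transitions are detected; per-event response changes are computed with
compartment-appropriate windows; and an ROC statistic with a permutation
null turns the two distributions of changes into a single selectivity
index per neuron or voxel.

## Song-event processing

**Median smoothing.** Classifier errors are typically isolated samples, so
each class's binary indicator is median-filtered with a class-specific
window (pulse 17.6 ms, sine 25.6 ms, flight 80 ms). Windows are converted
to sample counts on the 1.6-ms grid as the nearest odd integer with ties
resolved downward (11, 15 and 49 samples) because an even-length median
has no unique center; track ends are padded by edge replication. After
filtering, one label per sample is resolved with the fixed priority
flight > pulse > sine > others > ambient. The filter is applied once; on
tracks whose bouts are long relative to the window (every realistic track)
a second pass changes nothing, but idempotence is not a mathematical
guarantee for adversarial inputs — pathological alternations can take two
passes to reach a fixed point, which is why the test suite checks
idempotence on generator tracks rather than on arbitrary strings.

**Pulse trains.** Pulse song is a train of discrete events; to compare its
extent with continuous sine song, pulse segments separated by gaps of at
most 50 ms are merged into pulse trains. The merge is a left-to-right
union; the tests verify equivalence with a fixed-point pairwise merge on
random segment lists.

**Frame binning.** Imaging runs at 7.1 volumes/s, so labels are reduced to
the frame grid by averaging per-class occurrence (or classifier
probability) within each frame interval `[t_k, t_{k+1})`. A class occurs
in a frame iff its mean strictly exceeds its threshold — pulse 0.1, sine
0.6, ambient 0.9, flight 0.01. The pulse threshold is deliberately
permissive because pulses are sparse within trains; for the same reason
the frame state is resolved with priority flight > pulse > sine > quiet.
Frames with no active flag (or outside the track span) are "undefined" and
can never participate in a transition. Frames are defined by acquisition
timestamps rather than a hard-coded 141.0 ms: 1/7.1 Hz = 140.8 ms and the
frame period is not an integer multiple of the label period, so the
nominal 141-ms figure is treated as descriptive.

**Flight exclusion.** Flight contaminates both the song microphone and the
imaging, so any frame whose interval intersects a flight frame padded by
1 s on each side is masked. Masked frames contribute to no downstream
statistic; transitions require both boundary frames unmasked and no
gap-bridging is performed. Masking is monotone: adding flight can only
remove transitions, a property the suite checks explicitly.

**Transitions.** A pulse→sine event exists at every boundary where frame
k is pulse and k+1 is sine (and symmetrically); the event's bout lengths
are the contiguous same-state runs on either side. Quiet→pulse events
require at least 2 s of uninterrupted quiet before the pulse frame. Bouts
are tagged short/long against 422 ms (pulse) and 704 ms (sine); both
thresholds are exact frame multiples, so the tie rule is "strictly longer
= long".

## Calcium statistics

**ΔF/F.** Baselines are per trial — the mean F over the 10 s preceding
each stimulus onset — because trials are 20 s apart and slow drift
(bleaching) would contaminate a global baseline. ΔF/F is invariant under a
common positive gain on F, which the tests assert.

**Transition responses.** The response to a transition is
`δ = mean ΔF/F(post) − mean ΔF/F(transition window)`, where the transition
window is the last old-state frame and the first new-state frame, and the
post window counts the first new-state frame as +1: soma uses frames
+3/+4 (282–564 ms after the change) and neurites +2/+3 (141–423 ms),
reflecting their faster indicator kinetics. Events whose windows contain
masked or missing frames are dropped. The normalized change per ROI and
transition kind is `mean(δ) / mean(transition-window ΔF/F)` and requires
at least 5 events and a transition-window mean of at least 0.1 — below
that floor the ratio is numerically unreliable and the ROI is excluded
rather than reported. Quiet→pulse changes use ±2-s windows and require 2
events. Events whose windows cross a stimulation onset or offset are
retained, since singing occurs within constant stimulation epochs.

**Decay kinetics.** The half-decay time is obtained by fitting
`a·exp(−r·t)` over 845 ms (six frames) of the across-event mean time
course — not per event, where noise would dominate — with
Levenberg–Marquardt least squares, amplitude initialized at the first
point and rate at 1/s; `t½ = ln 2 / r`. Non-decaying fits (r ≤ 0) are
flagged and the half-decay left undefined instead of reporting a negative
time.

## The song-type preference and its nulls

Selectivity is the ROC statistic: with X the ΔF/F changes at sine→pulse
transitions and Y those at pulse→sine, `AUC = P(X > Y) + ½·P(X = Y)` over
all pairs (midrank tie handling; the implementation uses the rank-sum
identity and the tests compare it against a literal pairwise loop), and
`S = 2·AUC − 1`. S is antisymmetric under swapping the two samples and
invariant under any strictly monotone transform of all changes.

The per-ROI null shuffles the transition-kind labels, preserving group
sizes, and uses the add-one two-sided p-value
`p = (1 + #{|S₀| ≥ |S|}) / (1 + B)`, which can never be exactly zero and
keeps the test exact-level. The default B is 10,000; the calibration
studies use B = 1,000 for speed, which changes the granularity of p but
not its validity.

For voxel maps the statistic is the mean transition response after
sine→pulse minus that after pulse→sine, using the soma post-window — the
voxel-wise window is not separately specifiable in the source analyses, so
the slower-compartment window is the conservative choice. The null is
formed by **trial shuffling**: whole calcium trials are permuted relative
to the song trials, so each event reads its windows at the same
within-trial position of a random other trial. This preserves all
within-trial autocorrelation of the calcium signal while destroying its
pairing with behavior — a stricter null than IID label shuffling. The
identity alignment reproduces the observed statistic exactly, and only
events whose windows fit inside the common trial length participate.
Voxels are called significant at p < 0.001 per voxel; no spatial or
multiplicity correction is applied beyond that per-voxel threshold.

With B = 1,000 shuffles the smallest attainable p is 1/1001, so the true
per-voxel false-positive rate at the 0.001 threshold is 1/1001 ≈ 0.000999.
Over any desk-scale number of voxel tests the observed false-positive
fraction is then a small-count binomial draw whose median sits essentially
on the nominal line; the calibration test therefore checks that the
observed count does not exceed the upper 99.9% binomial envelope at the
nominal rate, which is the sharpest check that does not fail by sampling
noise alone.

## Behavioral statistics

Transition probabilities are defined on the classifier grid itself: for
every sample in a source state (quiet, pulse, sine) the "event" is the
state of the *next 1.6-ms sample*. This makes the estimates scale-free
per-sample hazards — exactly the quantities the geometric-dwell generator
parameterizes — while the 150-ms bins are only the stimulus-locked
reporting grid over which counts are pooled (across trials and flies).
Bins with no source-state occupancy are reported as missing, never imputed
as zero. Song fractions use pulse-train membership (not raw pulse labels)
so pulse and sine amounts are on the same footing. Stimulation effects are
per fly, `during − pre` with a 5-s pre-window; the sign convention is
chosen so that positive means the stimulus increased the statistic.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with defaults chosen once as plausible study conditions:

* **Song states** follow a per-bin Markov chain over quiet, pulse, sine
  and flight with separate transition matrices for stimulation-on and
  stimulation-off bins; the schedule defaults to 10-s constant-stimulation
  trials with 20-s inter-trial intervals. Dwell times are geometric
  (memoryless) so that the per-bin hazard the behavioral estimators
  recover has a closed form; default mean dwells during stimulation are
  0.5 s (quiet), 0.7 s (pulse) and 1.0 s (sine) — bout lengths of order
  0.1–3 s, pulse bouts shorter than sine bouts — and outside stimulation
  song collapses (0.3-s song dwells, 60-s quiet dwell). Flight is off by
  default and exists only to exercise the masking logic.
* **Classifier tracks** put probability mass U(0.6, 0.9) on the reported
  class and spread the rest evenly; with flip noise ε the reported class
  is wrong with probability ε, giving a binomial oracle for the argmax
  error rate.
* **Calcium traces** are `F(t) = F0·(1 + (g ⊛ k)(t)) + N(0, σ²)` at 7.1
  frames/s, where g is the state-gated gain sequence and k a unit-peak
  difference-of-exponentials kernel (rise 0.05 s, decay 0.5 s by default —
  fast-indicator kinetics). The convolution is discretized with the
  1.6-ms label period as integration step, so a sustained unit gain
  saturates near `τ_d − τ_r ≈ 0.45` ΔF/F — a realistic response
  magnitude. Noise is additive Gaussian on F (σ defaults to 0.05·F0), the
  simplest model consistent with shot-noise-dominated imaging. The model
  deliberately omits optics, indicator nonlinearity, saturation,
  bleaching and motion.
* **Voxel movies** share one clean trace per tuning cluster with
  independent per-voxel noise; a single-voxel layout reproduces the trace
  generator sample for sample under the same seed.
* **Toy connectomes** draw Poisson synapse counts (one mean within
  groups, another between) and per-synapse transmitter probabilities from
  a Dirichlet around each group's profile.

Because the generator is memoryless and its calcium model linear, passing
the calibration studies shows that the estimators are unbiased and the
nulls exact *under these assumptions*; it does not certify behavior under
real-data features such as non-stationary singing, indicator saturation,
or motion artifacts.

## Numerical choices and study sizes

* Threshold comparisons are strict (`>`); bout-length ties go to "short".
* The AUC uses midranks, so S is exact under ties.
* Permutation p-values use the add-one form and a 1e-12 comparison
  tolerance so that rank-arithmetic round-off cannot flip an exceedance.
* The decay fit falls back to a log-linear fit if the nonlinear solver
  fails on all-positive data.
* Degenerate inputs fail loudly: empty delta lists, single-trial shuffles,
  zero-variance responsiveness tests and non-positive baselines are
  errors, not silent NAs; empty behavioral bins are NA by design.

The calibration studies run at sizes chosen to give stable rates on one
CPU: 1,000 random instances for each brute-force oracle (transition
strings up to 2,000 frames), 500 exchangeable neurons at 4 trials each
with 1,000 permutations for the type-I study, 100 seeded runs at 14
trials (≈30–40 events per transition kind) for the sign-recovery and
delta-pattern studies, 10 + 3 movie seeds of 16×16 voxels binned 2×2 with
1,000 trial shuffles for the voxel calibration, and 100 two-block
connectomes. The permutation count is the one calibrated quantity reduced
from the 10,000-permutation default, which changes only the p-value
granularity.

## Known limitations

* The voxel-map window reuses the soma post-window for all voxels;
  neuropil-dominated voxels would be served better by the neurite window.
* The trial-shuffle null requires (approximately) equal trial lengths and
  discards events whose windows do not fit the shortest trial.
* The behavioral estimators assume the classifier grid is uniform; gaps
  in real exports should be split into separate tracks.
* Bout statistics near recording edges are truncated runs and are
  reported as observed, not extrapolated.
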
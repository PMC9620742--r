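---
title: "Methods: classifying and decoding movement-type signaling in lever-task calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying and decoding movement-type signaling in lever-task calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lever2p` analyses trial-structured population recordings from motor cortex
made while a head-fixed mouse performs cued push or pull movements of a
lever. The scientific questions it addresses are: which neurons are
movement-related at all; among those, which respond equivalently to both
movement directions ("movement-invariant") and which carry a push/pull
bias; when their responses start; how well movement type can be decoded
from single neurons and from the population; whether push and pull
population trajectories are separable in a low-dimensional state space; and
whether the informative neurons cluster spatially.

Because no recordings ship with the package, a synthetic-session generator
with full ground truth defines the test bed. Everything below is organised
as: the model or procedure, its assumptions, the parameters that matter,
and the numerical decisions made where the procedure was genuinely open.

## The synthetic session generator

`generate_session()` emulates one field of view of a two-photon session at
40 Hz. Fluorescence for neuron $i$ is

$$F_i(t) = F_b\,[1 + s_i(t)] + \varepsilon_i(t),\qquad
\varepsilon_i(t) \sim \mathcal N(0, (\sigma F_b)^2)\ \text{i.i.d.},$$

with baseline $F_b = 100$ a.u. and noise $\sigma$ = `noise_sd` in
$\Delta F/F_0$ units (default 0.2 per frame). The planted signal $s_i(t)$
is a difference-of-exponentials calcium transient $e^{-t/\tau_d} -
e^{-t/\tau_r}$ (unit-normalised) with rise $\tau_r$ = 0.5 s, mimicking
GCaMP6s kinetics, and decay $\tau_d$ = 1.5 s, a typical GCaMP6s half-decay
choice; the decay is configurable because it is a generator choice, not a
measured constant. Each trial adds one transient at the (jittered) movement
initiation, scaled by the neuron's class amplitude for that movement:
invariant neurons use equal push/pull amplitudes (up- or down-modulated,
85%/15% by default, mirroring the reported split of increased versus
decreased invariant responses), bias types 1–4 use (increase, smaller
increase), (increase, nothing), (decrease, nothing) and (decrease, smaller
decrease) patterns, reward-phase neurons fire 1.1 s after movement
completion (the task's 1 s reward delay plus a short latency), and
non-responsive neurons carry baseline only. Suppressed amplitudes are
clamped at $-0.35\,\Delta F/F_0$ and the raw trace floored at 1 a.u. so
fluorescence stays positive; a suppression to $-1$ would mean total
darkness, which no real indicator produces.

Trials alternate push/pull with inter-trial intervals drawn uniformly from
4–6 s, reaction times U(0.2, 0.5) s and movement durations U(0.3, 0.6) s.
The emitted motion index is near zero during the ITI and rises exactly at
movement initiation, with small positive noise when `noise_sd > 0`. ROI
centroids are uniform over a 250 µm field of view, or clustered per class
when `spatial_clustering` is on.

The default effect amplitude (1.0 $\Delta F/F_0$) is five times the frame
noise SD. That ratio is the study condition under which classification
recovery is assessed; per-frame it is a strong but realistic single-cell
response, and across 40 trials the per-frame standard error of a mean
response is $\approx 0.03$, so detection operates at $\sim 30$ standard
errors while contrasts between bias types operate at $4$–$11$.

What the generator does *not* emulate: neuropil contamination, motion
artifacts, bleaching, correlated (shared) noise across neurons, and
behavioural variability in movement kinematics. Tests passing on this
generator therefore validate the statistical machinery and its
calibration, not robustness to those real-data nuisances, which the
upstream preprocessing this package deliberately excludes (registration,
decontamination, spike sorting) is meant to handle.

`generate_ramp_calibration_set()` produces the onset-calibration design:
cells whose trials are a flat baseline followed by a linear ramp of 0.5 s
rise at a known onset, plus noise — 100 cells with 30 trials each in the
reference design, sampled at 30 Hz.

## Signal preparation

The **motion index** is the sum over forelimb-ROI pixels of squared
consecutive-frame intensity differences. **LOESS smoothing** is local
linear regression with tricube weights over a fixed window in seconds
(1 s for the motion index and for peri-movement traces); boundary windows
are truncated rather than padded. The fixed-window form is implemented
directly (as a precomputed linear smoother for uniform grids) because the
nearest-neighbour span of `stats::loess` does not have time-window
semantics.

**$\Delta F/F_0$**: $F_0$ is the 5th percentile of the 1 Hz low-pass
filtered raw trace, with the low-pass realised as a zero-phase
second-order Butterworth filter (the cutoff is given; the filter family is
a documented choice). The input is reflection-padded before `filtfilt` to
suppress edge transients, which otherwise corrupt the percentile.

**Motion-index onsets** (imaging mode): the baseline is the 1.5 s of ITI
before the cue; the threshold is the upper bound of a 10,000-sample
percentile bootstrap CI of the baseline mean of the smoothed motion index,
and the candidate onset region is the suprathreshold run leading into the
lever movement. Because a 1 s smoother spreads the movement pulse
backwards by up to half a window, the onset is then refined within that
run to the first point where the *raw* motion index departs from baseline
(mean + 2 SD) and stays above it for 75 ms — the sustained-run condition
keeps isolated noise excursions from backdating the onset. With zero
noise this recovers the generating initiation
time exactly; at the default noise level the median error is below one
frame with an occasional early tail of a few frames. Ephys mode follows
the simpler rule appropriate for high-rate behavioural sampling: first
crossing of baseline mean + 2 SD after the cue, with trials already above
threshold at the cue flagged for exclusion.

Alignment copies frames without interpolation (time zero at the event;
windows half-open, frames 0-based, all times in seconds, all distances in
µm). Out-of-range trials are kept as NA and flagged, never silently
dropped.

## Response classification

Epochs relative to motion-index onset: baseline $(-0.50, -0.15)$ s,
peri-movement $(-0.15, \text{median completion} + 0.04)$ s, analysed in
250 ms bins (full bins only). Two independent bootstrap tests (10,000
trial resamples each) decide responsiveness per movement:

1. *Baseline-to-peak*: each resample averages the resampled trials,
   locates the largest absolute deviation from the baseline mean within
   the peri-movement window, and takes the mean of the 100 ms centered on
   it minus the baseline mean. Significant if the 95% percentile CI
   excludes zero. Using the largest *absolute* deviation makes suppressed
   responses detectable.
2. *Binned means*: the bootstrap distribution of each 250 ms bin mean is
   compared with the bootstrap distribution of the baseline mean; a bin is
   significant when the two 95% percentile CIs are disjoint.

A neuron is responsive if either method fires. "Compared" admits two
readings — a CI on the difference of means, or non-overlap of the two
CIs. Non-overlap is implemented: it is the convention this analysis
family states explicitly for its spiking-unit bias rule, and it is the
only reading whose combined false-positive rate stays in the low single
digits (measured 2–3% on pure-noise neurons, and ~5% for the bias
contrast on strong invariant responses); a difference-CI reading runs
each of roughly four effectively independent bin/method tests at 5%,
compounding to a 10–15% per-neuron rate, because no multiple-testing
correction is applied across bins. Power is not a concern either way:
planted effects at the study conditions sit 10–30 standard errors from
the null. Neurons with fewer than 5 trials per movement are marked
unclassifiable rather than guessed.

**Reward-phase screening.** Reward responses begin about 1 s after
movement completion, i.e. after the peri-movement epoch ends, so they can
never reach significance under the movement-epoch tests; yet the taxonomy
requires them to be identified (and excluded from movement analysis).
Neurons silent in the movement epochs are therefore screened once more
with the baseline-to-peak method only over a post-movement reward window
(default 2.5 s). Method 1 alone is used there because a multi-bin screen
over a long window would multiply null chances to fire. The final arbiter
stays the onset rule: significant neurons whose median response onset
falls after median completion + 40 ms (a GCaMP-rise allowance) are
reward-phase; later-onset detection failures default to movement-related.

**Bias.** Movement-related neurons are tested for a push/pull contrast
with the same two methods applied across movements: the difference of the
movements' bootstrapped baseline-to-peak values (CI versus zero), and
per-bin comparison of baseline-corrected bin means via disjoint CIs
(baseline subtraction keeps resting-level
differences between trial types out of the bias test). Significant neurons
are biased toward the movement with the larger absolute baseline-to-peak
response; otherwise they are movement-invariant. Bias types follow the
sign taxonomy: increases in both movements (1), a selective increase (2),
a selective decrease (3), decreases in both (4). Two conventions had to be
fixed: which selective pattern is "type 2" versus "type 3" (resolved by
sign: increase = 2, decrease = 3), and the unnamed mixed increase/decrease
pattern (mapped to type 2, since a selective increase exists); both are
documented at `assign_bias_type()`.

**Spiking units** follow the electrophysiology variant: rates from a 50 ms
Gaussian kernel, baseline 1 s before the cue, 250 ms bins tiling the
response period back from the latest median completion so the onset bin is
included, bootstrap CIs per bin, bias when push and pull CIs are disjoint
in a responsive bin. Putative pyramidal units are those with median spike
width strictly greater than 0.4 ms.

## Onset detection (slope sum function)

Traces are Savitzky-Golay smoothed (27 frames, order 2), differentiated,
negative slopes clipped to zero, and summed over a trailing 375 ms window
(the SSF). The onset is the earliest point where the SSF exceeds 10% of
its peak, walked back to the preceding local SSF minimum. A trace whose
SSF peak does not exceed three times its median SSF level (or is zero up
to filter roundoff) yields no onset.

The neuron-level onset bootstraps trials 10,000 times; each resample
averages the smoothed trials and the onset is detected on that mean trace,
the neuron onset being the median over resamples. The resample-averaged
form is used because at realistic noise single-trial threshold crossings
are dominated by noise excursions (biases of several hundred ms), which
is precisely what the bootstrap is meant to suppress. Missing onsets are
excluded, never imputed; a neuron needs at least half of its resamples to
yield an onset.

Savitzky-Golay smoothing plus the walk-back rule backdate onsets by an
amount that depends only on the filter and decision rule, so the detector
is calibrated on the ramp design: `calibrate_correction()` returns the
median signed error over cells, which is then subtracted from all detected
onsets. After calibration the held-out median absolute error is below one
frame at 30 Hz at matched noise. Onset estimates are invariant to positive
affine scalings of the trace because the threshold is a fraction of the
peak.

## Decoding

**Single neurons.** At each frame of a 5 s peri-movement window, trials
are decoded leave-one-out with a Gaussian naive-Bayes rule: per-class
mean and variance at that frame (variance floored at $10^{-6}$ to keep
degenerate training sets defined), empirical class priors, maximum
posterior. The per-neuron summary epoch starts at $-0.15$ s and ends at
the later of the two per-movement median peak times. The session
significance threshold is simulated: 1000 label-free datasets of standard
Gaussian features with the session's trial counts, decoded with the same
rule under a 50:50 prior; the threshold is the null mean + 2 SD. A neuron
is "high decoding accuracy" (HDA) when at least one 250 ms bin's
bootstrap CI lower bound exceeds the threshold (10,000 resamples; the
bootstrap count is unstated in the source procedure and set to match the
rest of the package). On null sessions the decoder's mean accuracy sits
slightly below 0.5 (the usual leave-one-out pessimism) and the HDA false
positive rate stays below 10%.

**Population.** Leave-one-out logistic regression on the population
vector, with per-feature standardization and a weak L2 penalty
($\lambda = 1$ on standardized features) for stability when neurons
outnumber trials; the fit is solved in the right-singular basis of the
feature matrix, which is exact and inexpensive for $n \ll p$. The
accuracy time series is computed per frame; the summary is the maximum
accuracy over 250 ms bins in the peri-movement epoch. For the
neuron-removal analysis the decoder is retrained from scratch after each
removal (descending single-neuron accuracy with ties broken by index, or
random order with the median over 25 repetitions); to keep 1300 retrains
tractable the removal summary is evaluated on 250 ms bin-averaged
features — the summary statistic is a bin accuracy in any case. The
chance reference samples 1000 random time points with permuted labels;
`proportion_to_chance` is the fraction of neurons removed when the
accuracy CI first overlaps the shuffle 95% CI. On sessions with 10
informative neurons out of 50, ordered removal reaches chance after about
a fifth of the population is removed while random removal needs most of
it.

## Population trajectories and separability

Successful trials over a 7.5 s peri-movement window are concatenated,
boxcar-filtered (3 frames), whitened per neuron — implemented as
z-scoring, the simplest reading of "whitened", with full ZCA left as an
explicit non-default — and projected onto the 16 leading principal
components. Mean push/pull trajectories carry 100-fold bootstrap CIs.
Separability per PC is
$d'(t) = |m_\text{push}(t) - m_\text{pull}(t)| / \sqrt{\tfrac12
(v_\text{push}(t) + v_\text{pull}(t))}$
with trial means and variances, bootstrapped from 400 within-class
resamples, against a trial-shuffled counterpart. How to turn the two
bootstrapped $d'$ series into a single separability verdict is a genuine
design choice: a per-frame any-crossing rule would have an uncontrolled
family-wise error over correlated frames. The implemented rule compares
the window-maximum $d'$
with the window-maximum shuffled $d'$ and declares a PC separable when
the difference minus 1.96 times the summed bootstrap SD stays above zero.
Under label shuffling this declares fewer than 7% of PCs separable;
frames with zero pooled variance are flagged NA rather than propagated.
The assessment window runs from movement onset to the longest movement
duration in the session.

## Spatiotemporal statistics

Pairwise Pearson correlations are computed between trial-averaged,
1 s-LOESS-smoothed peri-movement traces, per movement — the trial-averaged
form matches the peri-movement activity patterns the analysis describes —
together with Euclidean centroid distances. Note that 1 s smoothing of a
1–2 s epoch leaves few effective samples, so even independent neurons show
broad correlation distributions; comparisons are therefore always made
between groups under the same smoothing, never against a nominal null.
Bootstrapped median differences (10,000 resamples) compare HDA pairs with
the population (or with LDA pairs). Trial-to-trial similarity is the mean
Pearson correlation over all within-movement trial pairs of smoothed
single-trial traces, summarised by class as bootstrap medians (10,000
repetitions, 50 samples, equal weight per animal — the original weighting
is unspecified). The population-versus-behaviour analysis correlates
trial pairs of the summed movement-related $\Delta F/F_0$ against trial
pairs of the motion index, binned by the latter.

Spatial clustering is tested with a REML linear mixed model,
`r ~ distance * accuracy + (1 | movement) + (1 | animal)`, with decoding
accuracy standardized for numerical stability and a pair's accuracy taken
as the mean of its members' maxima. Random terms with a single level or a
singular variance estimate are dropped (flagged in the result), falling
back to an ordinary linear model when none remain — with two movement
types the movement intercept is frequently near-singular, and silently
keeping it would only destabilise the fixed-effect standard errors the
test depends on. On null pair tables the distance slope estimate stays
within two standard errors of zero, and injected slopes are recovered in
sign and magnitude.

## Problem sizes and reproducibility

The packaged analyses run on synthetic sessions of 50–100 neurons and
40–80 trials, with the bootstrap counts of the original procedures
(10,000; 1000 null decoder datasets; 400 d' resamples; 25 random removal
repetitions) — sizes chosen so a full session analysis completes in
minutes on one core while every procedure runs at its nominal resample
depth. All stochastic steps take explicit seeds; identical seeds give
bit-identical sessions, bootstrap CIs and pipeline outputs.
`run_pipeline()` stamps every output table with the seed and a hash of
the configuration. The session container is a directory of CSV and JSON
files (matrices, trial table, centroids, metadata) so results remain
inspectable by any toolchain.

## Known limitations

Reward-phase identification depends on the post-movement screening window
and the onset detector succeeding; a reward neuron whose onset cannot be
detected is conservatively labelled movement-related. The responsiveness
and bias rules apply no correction across bins; their type-I error is an
empirical property of the CI non-overlap comparison (measured 2–5%), not
a nominal level. The generator's i.i.d. noise understates shared
variability, so
decoding and correlation results on synthetic data are upper bounds on
what identical parameters would give with correlated noise. The mixed
model treats pairs as exchangeable observations; the dependence induced
by shared neurons is absorbed only through the random intercepts.
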
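---
title: "Closed-loop feedback perturbation and song-system physiology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop feedback perturbation and song-system physiology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songgate)
```

## The scientific problem

Adult zebra finches maintain their stereotyped song using auditory
feedback: deafening or chronically distorting what the bird hears degrades
song over days. A central question is *where* feedback meets the vocal
motor system. The sensorimotor nucleus HVC contains projection neurons
(HVC~X~ cells) that innervate a basal-ganglia pathway required for vocal
plasticity, fire in precisely song-locked patterns, and can respond to
playback of the bird's own song (BOS) when it is not singing. Whether
their *synaptic* inputs carry real-time feedback during singing can be
tested by delivering distorted auditory feedback (DAF) -- a brief noise
burst or syllable copy triggered on a targeted syllable -- on randomly
interleaved "hit" trials while recording intracellularly, and comparing
membrane potential against interleaved "catch" trials without playback.

`songgate` implements that entire experimental computation as a tested,
reusable pipeline: the online acoustic detector and closed-loop
controller; the intracellular analyses (hit-minus-catch membrane-potential
differences, depolarizing-postsynaptic-potential (dPSP) onset detection and
clustering, event-triggered dPSP rates); playback-response statistics;
dendritic-spine photometry from longitudinal two-photon stacks; and
song-degradation metrics. Because the original in vivo recordings are not
available as data files, every stage is paired with a synthetic-data
generator with exact ground truth, so each analysis can be validated
end-to-end.

## Acoustic front end

The online detector computes features in 5-ms windows updated at 1 kHz.
Each window receives a multitaper spectral estimate: the average of
periodograms over the first two Slepian (DPSS) tapers with time-bandwidth
parameter NW = 4, zero-padded to 512 FFT points at 44.1 kHz (256 points at
22.05 kHz, preserving the bin width). The tapers are computed from the
standard symmetric tridiagonal eigenproblem and are cross-checked in the
test suite against an independent reference implementation.

Per-frame features:

* **amplitude** -- total one-sided spectral power in dB re full scale
  (the spectrum is Parseval-scaled, so this equals tapered-window energy);
* **mean frequency** -- power-weighted centroid over the 0.5--10 kHz
  analysis band;
* **Wiener entropy** -- log ratio of geometric to arithmetic mean of
  in-band power; 0 for a flat (noise-like) spectrum, strongly negative for
  tonal sounds, capped at -25 log units for degenerate line spectra;
* **frequency modulation (FM)** -- the angle between the temporal and
  spectral derivatives of the log spectrum across consecutive frames;
* **pitch and goodness** -- the fundamental period estimated as the first
  strong peak of the normalized autocorrelation of the raw window within
  a 0.4--6 kHz search band (parabolically interpolated); goodness is the
  peak correlation in [0, 1]. A cepstral peak was considered first, but
  with a 5-ms window the NW = 4 multitaper smoothing (~800 Hz half-width)
  erases the harmonic ripple the cepstrum relies on, and prototype tests
  mis-estimated most harmonic-stack fundamentals; the autocorrelation
  convention recovered all of them, so it is the package's convention.
  The band limits and the FM/pitch definitions are conventions of this
  package, not facts inherited from any particular recording system.

Sound events are maximal runs of frames whose amplitude exceeds 10 times
the baseline noise amplitude (+20 dB over the noise floor, estimated as
the median of the quietest decile of a leading calibration segment). At
each event offset the per-event summary -- mean and (population) variance
of the five features plus duration, an 11-dimensional vector -- feeds the
syllable classifier.

## Syllable classification

Events are labeled (introductory note, individual syllables, cage noise)
by a Gaussian-kernel soft-margin SVM on z-scored summaries.
Hyperparameters (cost in {1, 10, 100}, kernel width gamma in
{0.5, 1, 2}/d) are selected by grid search inside stratified 5-fold
cross-validation; rows are first sorted into a canonical order so that CV
accuracy is exactly invariant to the order training examples arrive in.
Mirroring the deployment rule used for online detection, a model is
flagged deployable only when cross-validated accuracy reaches 98%.

## The closed-loop controller

The controller is a discrete-time simulation on the 1-ms frame clock (no
real-time audio hardware is involved):

1. completed sound events are classified; detecting the **pre-target
   syllable** at an event offset arms the target detector;
2. the **target onset** is declared when the amplitude criterion has held
   continuously for at least 3 ms. On a 1-ms clock this yields a
   detection-to-trigger latency in [3, 4) ms depending on the phase of
   criteria onset relative to the frame grid. If the criteria are not
   satisfied within ~100 ms the detector disarms and resumes pre-target
   search;
3. each trigger is assigned to **catch** with probability 0.5 (playback
   suppressed) or **hit** (playback after a uniform 8--10 ms delay;
   100-ms stimulus);
4. an optional **contingency rule** (e.g. "mean frequency below 5000 Hz
   escapes") gates playback for pitch-shifting protocols: values strictly
   on the non-escape side play; ties escape; an unmeasurable feature
   defaults to play.

Trial outcomes are classified against the motif grammar: a hit is
*truncated* when the expected next syllable is absent within a 500-ms
search horizon, *delayed* when its latency exceeds the 99th percentile of
the catch-trial latency distribution, and *normal* otherwise. The
truncation rule deliberately keys on absence rather than on a
median + 3 SD latency window: combined with the 99th-percentile delay
criterion, a latency window would leave a ~0.7-SD sliver in which a sung
but late syllable could be called "delayed", with anything later
miscalled "truncated" despite having been sung. Because DAF can delay
syllables, hit/catch comparisons can be balanced by retaining each hit
with probability min(1, p(tau | catch)/p(tau | hit)), estimated from
5-ms-bin histograms (empty catch bins reject); the retained hits' latency
distribution then matches the catch distribution within binomial error.

### Detection noise

Real sessions targeted a 50% hit rate but observed 30--70%, for reasons
the original description leaves open. The simulator therefore exposes a
single detection-noise knob rather than a mechanistic miss model:
Gaussian noise (default 1.0 training-set SDs per feature) is added to
event summaries before online classification. At the default, end-to-end
target detection efficiency is ~70--80% and the observed hit rate at 50%
catch probability falls in the mid-30s percent -- inside the reported
operating band, and realistically below the ideal 50%.

## Intracellular analyses

* **Despiking** -- 5-ms sliding median (shrinking window at the edges).
* **Spike detection** -- zero-phase 4th-order Butterworth high-pass at
  400 Hz; one spike per contiguous excursion of the fast component above
  +30 mV, timed at the peak. The criterion's published phrasing admits a
  second reading (deviation of the raw trace from its low-passed
  complement); both are implemented behind a `method` flag and agree on
  the synthetic fixtures.
* **State statistics** -- firing rate and despiked-Vm means in a 0.5-s
  pre-song window (-1 to -0.5 s before bout onset; a bout starts at the
  first syllable preceded by >= 1 s of silence) and a 0.5-s singing
  window (0--0.5 s), the transition excluded, over at most the first 50
  bouts.
* **Hit-minus-catch difference** -- per trial, the baseline is the mean
  Vm over -200..0 ms before DAF onset;
  Delta Vm(t) is the difference of trial-averaged baseline-subtracted Vm
  between hit and catch trials. Per-trial means over the fast (20--60 ms)
  and slow (60--200 ms) post-DAF windows are compared with two-sample
  Welch t-tests (hit and catch trials have no natural pairing), and the
  minimum of the two window p-values is reported. Trials can be grouped
  into 5-mV baseline-voltage bins; groups with fewer than 14 total motifs
  are excluded with a recorded reason. Identical hit and catch sets give
  Delta Vm = 0 and p = 1 by construction.
* **dPSP onsets** -- the slope (V(t+dt) - V(t))/dt with dt = 4 ms is
  computed on a locally averaged trace (dt/2 boxcar) and thresholded at
  1.5 times its SD over the segment, with 5-ms refractoriness; crossings
  are attributed to the end of the difference window. The default sits at
  the top of the conventional 0.8--1.5 range because on segments where
  sharp rises occupy a small fraction of time the slope SD is
  noise-dominated, and a 1.0x threshold admits several false positives
  per second; at 1.5x a seeded sweep recovers 100% of injected onsets
  within +/-2 ms at amplitude-to-noise ratios >= 4 with 0.15 false
  positives/s. Only sharp-rising dPSPs are detected by design.
* **Onset clustering** -- onsets 20--200 ms after DAF onset are clustered
  by k-means on onset time (k chosen by inspecting the onset histogram);
  per cluster, hit and catch member times are compared by t-test.
* **Event-triggered dPSP rate** -- histogram of onset-minus-anchor lags
  (5-ms bins) normalized by anchor count and bin width; synaptic drive
  leading syllable onsets by ~25 ms appears as a peak at -25 ms.

## Playback responses and mirroring

Responses in non-singing states are assessed from >= 7 artifact-free
trials by a two-stage procedure: a Mann-Whitney U-test on the per-trial
response vs baseline values; only if that is not significant, an
Ansari-Bradley variance test (which presumes comparable medians). Either
test below p = 0.025 marks the cell responsive, and the response index
|r_response - r_base| / |r_response + r_base| is computed from the means
(median route) or SDs (variance route). The index's published numerator
contains an obvious typo (it would be identically zero); the difference
form is used. Auditory-vocal "mirroring" is the Pearson correlation of
motif-aligned average Vm during singing versus during playback, with no
time warping.

## Spine photometry

The generator renders a dendritic segment and spine heads as 3D Gaussians
(intrinsic size convolved with the PSF) on a voxel grid with mixed
Poisson-Gaussian noise; between sessions spines are lost with a per-2-h
probability and surviving intensities scale as `size_scale_per_24h^(t/24)`.
Spine size is the background-subtracted integrated optical density over
the head ROI normalized to the background-subtracted mean of a ~2-um
adjacent shaft segment; the size index is the 24-h ratio and stability
the percentage of spines maintained across 2 h. The background ROI is a
large empty-margin slab: because the background estimate is subtracted
once per head voxel, its error enters every spine of a session
coherently, and a small ROI would bias whole-session size indices.
Smoothing is for detection only; measurements use raw intensities, making
all metrics exactly invariant to a global intensity gain.

## Song degradation

Per syllable rendition, entropy is the mean and EV the variance of
frame-wise Wiener entropy (computed with the package's own band and frame
conventions, so results are self-consistent). With ~30 renditions per
syllable per day and two pre-manipulation days pooled as baseline, each
later day is compared to baseline by one-way ANOVA (alpha = 0.05); the
onset of degradation is the earliest day that is significant *and remains
significant on every subsequent day*. A transient single-day deviation
therefore never yields an onset; and because persistence cannot be
assessed without at least one later day, the final observed day is never
an onset candidate by itself (otherwise a single chance-significant last
day among 2 x n_syllables comparisons would trigger a spurious onset with
high probability).

## What the generators emulate -- and what they do not

The song generator produces harmonic-stack syllables (raised-cosine
envelopes, entropy controlled by white-noise mixing, Gaussian tempo
jitter on gaps) over a calibratable noise floor -- enough structure for
feature extraction, classification and triggering, with exact onset/label
truth. It does not attempt realistic syrinx acoustics, within-syllable
frequency sweeps, or amplitude modulation depth, so passing tests
certify the *pipeline*, not acoustic generality. The membrane-potential
generator produces rest/singing states, difference-of-exponential dPSPs,
threshold-triggered and tonic Poisson spikes, and additive Gaussian
noise; it contains no conductances, and in its DAF-null mode hit and
catch epochs are statistically identical by construction, which is what
makes the type-I-error calibrations meaningful. The spine generator uses
ideal Gaussian optics with no motion, bleaching, or segmentation errors.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use desk-scale sizes chosen
to estimate each quantity comfortably within its tolerance: 2000
closed-loop renditions (binomial SE on the hit rate ~1 point), 200
replicates for type-I-error and resampling calibrations, 30--40 spines
per stability/size sweep, and 15--30 renditions per syllable per day for
degradation. Half-open intervals `[onset, offset)` are used throughout;
times are in milliseconds from recording start; seeds parameterize every
stochastic generator, and identical seeds give bit-identical outputs.

## Known limitations

Syllable segmentation is amplitude-threshold only (no merging of
sub-syllabic gaps); the controller's contingency window uses the offline
feature stream rather than a separate online estimator; k for dPSP
clustering is user-chosen, as in the original procedure; spine matching
across sessions assumes an already-aligned field of view; and the
degradation ANOVA applies no multiplicity correction across syllables or
features, matching the published rule.
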
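---
title: "Representational and directional-connectivity analysis of two-region working-memory recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representational and directional-connectivity analysis of two-region working-memory recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmcircuit)
```

## The analysis problem

`wmcircuit` analyses simultaneous local field potential recordings from
two medial temporal regions — an amygdala-like and a hippocampus-like
region, labelled `AMY` and `HIP` — while a subject performs a Sternberg
working-memory task. Each trial presents a set of 4, 6 or 8 letters for
2 s (encoding), holds them over a 3 s blank delay (maintenance) and
probes recognition afterwards, so the memory load is controlled and the
encoding and maintenance computations are temporally separated. The
pipeline asks three questions of such data:

1. **How distinct are the item representations a region forms during
   encoding?** Quantified by encoding–encoding dissimilarity (EED).
2. **How stable is the encoding representation across the delay?**
   Quantified by encoding–maintenance similarity (EMS).
3. **In which direction does band-limited information flow between the
   regions?** Quantified by the phase slope index (PSI) with a
   trial-shuffle surrogate.

A fourth, integrative question — do these measures carry information
about memory load? — is answered by a PCA + linear-SVM decoder.

## Signal conditioning

The preprocessing chain mirrors common intracranial practice: a
zero-phase band-pass FIR filter (Hamming window; the order is derived
from a transition bandwidth of 25% of each cutoff, so only the band
edges need specifying), line-noise removal by least-squares fitting and
subtracting the sine/cosine component at each mains harmonic over the
whole recording (a single-window DFT estimate; the paper-style method
leaves neighbouring frequencies untouched), anti-aliased downsampling,
and re-referencing each channel to the average of the artifact-free
("clean") channels. Downsampling uses a zero-phase Blackman-window FIR
anti-alias filter followed by integer decimation (Fourier-domain
resampling when the ratio is not an integer); the Blackman stopband
(~74 dB) keeps the summed alias images of a large decimation factor
below −40 dB.

Epochs are cut half-open at `[onset, onset + duration)` — 1 s fixation,
2 s encoding, 3 s maintenance, 2 s retrieval — plus a 500 ms pretrial
baseline ending at fixation onset. Manual artifact screening is
replaced by a reproducible rule: a trial is dropped when any channel's
peak amplitude exceeds `k = 8` times that channel's median absolute
deviation; an externally supplied keep-mask is also accepted. Analyses
run on correct trials.

## Time–frequency features

Power is computed by convolution with 6-cycle complex Morlet wavelets
at 1–100 Hz in 1 Hz steps, at full sample resolution. Task power is
z-scored against a bootstrap null of the baseline: for each channel and
frequency, 1000 replicates are formed, each the mean of `m` points
drawn with replacement from the pooled baseline samples of all kept
trials (`m` defaults to the number of baseline samples in one trial;
a per-trial bootstrap is available since pooling across trials is a
choice, not a necessity). The null's mean and standard deviation
z-score every task sample. Because both statistics scale linearly with
power, the z-scores are invariant to rescaling the raw signal. The
feature band for all representational analyses is the z-scored 1–40 Hz
power. Samples within half a wavelet of an epoch edge are flagged in an
edge mask; windows may include them, matching the tolerant default.

## Representational maps

A 100 ms window slides in 10 ms steps over each period, with centers at
both endpoints inclusive — 201 encoding windows and 301 maintenance
windows; edge windows are truncated to the available samples. Within a
window the z-scored power is averaged over time and vectorized over
channels × frequencies (channel-major). Two patterns are compared by
Spearman correlation (average ranks for ties) clipped to
±(1 − 10⁻¹⁰) and Fisher z-transformed.

* **EED**: for each pair of encoding windows, `1 − atanh(ρ)` between
  the patterns of two *different* trials, averaged over trial pairs and
  symmetrized over the two orderings. Uncorrelated patterns give 1;
  identical patterns a strongly negative value.
* **EMS**: for each encoding-window × maintenance-window pair,
  `atanh(ρ)` between the two patterns of the *same* trial, averaged
  over trials. (A dissimilarity variant `1 − atanh(ρ)` is available;
  the similarity form is the default.)

Internally all window-pair correlations come from one cross-product of
standardized rank matrices, which is algebraically identical to the
pairwise Spearman loop; the unit tests compare it against a brute-force
rank-then-Pearson oracle at 10⁻¹⁰.

For map-level group inference, `cluster_permutation_paired()`
thresholds pointwise paired t statistics at two-sided p = 0.05, forms
4-connected clusters separately for positive and negative exceedances,
scores each cluster by its summed t, and compares against the maximum
absolute cluster mass under per-participant condition sign flips (fully
enumerated for ≤ 12 participants, Monte Carlo otherwise); p-values use
(b + 1)/(m + 1) smoothing. The pointwise threshold and permutation
count are declared defaults, not inherited values.

## Directional connectivity

Per-trial segments are Hann-tapered and zero-padded to the smallest
multiple of the sampling rate at least twice the segment length, so
integer frequencies fall exactly on DFT bins (power-of-two padding
would put 1 Hz steps between bins). Cross- and auto-spectra averaged
over trials give the complex coherency `C(f)`, with the convention
`S_ab = <Fa conj(Fb)>`: delaying the second signal produces a positive
phase ramp. The phase slope index at centre `c` is

`psi(c) = Im( sum_f conj(C(f)) C(f + 1 Hz) )`

over bins within `c ± 2` Hz (the half-width is a parameter; bands are
truncated and flagged at the 1–40 Hz range edges). With the hippocampus
channel first, positive PSI means the hippocampus leads.

Significance uses a trial-shuffle surrogate: permuting the trial
pairing between the two channels destroys trial-locked coupling while
preserving each channel's spectrum; 200 shuffles per channel pair.
Observed PSI and the null replicates are averaged over the pooled
channel pairs (ipsilateral pairs only, hippocampus × amygdala), and
`z(f) = (obs − mean null)/sd null`, with hippocampus-leads declared at
z > 1.96 and amygdala-leads at z < −1.96.

**Known limitation.** The trial-shuffle null underestimates the
variance of the aligned-pairing PSI when the two channels share a
strong zero-lag component (shuffling removes the shared signal), so
very strong common signal inflates |z| symmetrically — without creating
a directional preference; the estimator itself stays unbiased at zero.
At leakage levels typical after common-average re-referencing (a few
percent of variance) the z-scores are calibrated; the tests check both
the unbiasedness under strong mixing and the calibration under weak
mixing.

## Load decoding

Features are one flattened map per sampling unit: EED per trial pair
(201² = 40401 values), EMS per trial (201 × 301 = 60501 values), or the
direction-rectified z-scored PSI per channel pair (hippocampus-leads
features keep positive z, amygdala-leads the magnitude of negative z,
so the two directions are disjoint by sign). Units are pooled across
sessions/participants per load. When pooling, `center_sessions = TRUE`
subtracts each session's overall feature mean first; this removes
random session offsets that otherwise dominate the feature space and is
label-blind, so it cannot manufacture class information.

Each of the (default 100) repeats draws a stratified split — 70% of
each load class for training, rounded down — standardizes with
train-fit statistics, fits PCA on the training block only and keeps
components up to 99% cumulative explained variance, projects the test
block with the train-fit transform, and scores a linear SVM (one-vs-one,
cost 1). A regression test guards the train-only PCA contract against a
deliberately leaky oracle. Accuracy differences between regions or
directions are assessed by shuffling labels (default 200 times) and
recomputing the difference; `accuracy_vs_chance_test()` does the same
against the 1/3 chance level. Standardizing before PCA is a package
choice, needed for scale-mixed PSI features and switchable off.

**A caution on pair-level features.** EED samples are trial *pairs*;
pairs sharing a trial are dependent, and a random pair-level split
places such relatives on both sides of the train/test boundary. On
synthetic data with no load effect at all, pair-level EED decoding
reaches ~0.47–0.50 "accuracy" through this trial-identity leakage. The
EED decoding surface reproduces the published design faithfully, but
chance-level calibration claims in this package are made with EMS
(trial-level) features, which have no such dependence.

## The synthetic session generator

`sim_config()`/`synthesize_session()` generate two-region sessions with
known ground truth. Defaults describe one study-like session: 17 trials
per load (~50 per session), 4 amygdala and 6 hippocampus channels at
1 kHz, 1/f background noise (exponent 1, 10 µV sd), optional mains
component, and:

* **Item patterns**: unit-RMS nonnegative vectors over channels ×
  integer frequencies 4–32 Hz, mixed per trial as
  `(1 − δ)·template + δ·independent` and renormalized, so δ is a single
  monotone distinctiveness knob (δ = 0: one shared template; δ = 1:
  independent patterns). Defaults δ(AMY) = 0.9, δ(HIP) = 0.2 — the
  distinct-amygdala / overlapping-hippocampus regime.
* **Maintenance persistence**: the maintenance pattern blends the
  encoding pattern with a fresh one in *power* space —
  `pm² ∝ ρ·pe² + sqrt(1 − ρ²)·q²` — because the analysis correlates
  squared-amplitude (power) patterns; this makes ρ the target
  power-pattern correlation exactly, linear over the whole range.
  ρ(HIP) = 0.8, ρ(AMY) = 0.1 — stable hippocampal, labile amygdalar
  maintenance.
* **Oscillation amplitude** 4.5 µV per unit pattern weight (scaled by the
  load gain), chosen so that task-induced z-power sits in the 5–15
  range typical of robust intracranial task responses and the δ/ρ knobs
  act monotonically on the measured EED/EMS. Phases are independent per
  channel × frequency, so the patterns carry no common component that
  re-referencing would cancel.
* **Coupling**: each entry adds narrowband Gaussian noise (20 µV sd) to
  the source region's channels — one independent component per source
  channel — and a copy delayed by `lag_ms` and scaled by `gain` to
  target channels (assigned cyclically). The cross-spectral phase slope
  is therefore analytic (2π·lag), and independent per-channel
  components survive common-average re-referencing, which would cancel
  a region-wide shared component. Defaults: hippocampus→amygdala at
  4–8 Hz and amygdala→hippocampus at 20–28 Hz, both 25 ms lag.
* **Load gain**: multiplicative pattern amplitude {4: 1.0, 6: 1.15,
  8: 1.3}; setting all gains equal creates the null-load regime used
  for chance calibration.

All randomness flows from `seed`; identical configurations reproduce
sessions bit-for-bit.

**What the generator does and does not emulate.** It reproduces the
statistical structure the analysis assumes — region-specific pattern
distinctiveness and persistence, lagged band-limited coupling, load
modulated amplitude — but not biophysics: no epileptiform activity, no
evoked transients, no cross-frequency coupling, no nonstationary noise.
Passing recovery tests therefore shows the pipeline measures what it
claims on data satisfying its assumptions, not that real recordings
satisfy them. Three emergent properties are worth noting. A common
frequency-response profile shared by all trials — the wavelet bandwidth
and the baseline-null standard deviation both vary systematically with
frequency — sets a floor on cross-trial rank correlations and
compresses the dynamic range through which the distinctiveness and
persistence knobs act; this is intrinsic to baseline-z-scored band
power, not an artifact of the generator, and it is why the recovery
experiments average several sessions per simulated participant (as
multi-session studies do). Second, because
wavelet-power estimation noise is multiplicative, a pure amplitude gain
moves the rank-correlation features only weakly; the load effect is
detectable, but only with the default channel counts and ~50-trial
sessions pooled over several sessions — thin two-channel sessions
cannot resolve it. Third, a multiplicative gain raises the effective
SNR of *both* regions' patterns, and correlation features respond to
SNR most strongly where trial patterns are most similar; the generator
therefore does not reproduce the published region ordering of decoding
accuracies (EED decoding best in the amygdala), which in real data
presumably reflects mechanisms beyond a global amplitude gain. The
package tests the orderings the generator does control (EED/EMS map
contrasts, PSI directions, load detectability and its null).

## Numerical choices and problem sizes

Spearman ties use average ranks; correlations are clipped at
±(1 − 10⁻¹⁰) before `atanh`; zero-variance feature vectors raise a
degenerate-correlation error rather than returning NA. The baseline
bootstrap requires nonzero variance and errors on degenerate input.
Window grids include both period endpoints (forced by the 201/301
counts); map entries at truncated edge windows use the available
samples. EED used for decoding is computed within load; the
region-contrast map pools all correct-trial pairs.

The test suite and the acceptance script run the full method at reduced
problem sizes — 200 Hz sampling, 2 channels per region for the map and
PSI recovery experiments (the generator's default channel counts and
17 trials per load are kept where the experiment needs them, e.g. load
decoding), 100 ms window steps for recovery maps, 200-replicate
baselines, and 40 × 40 maps with 8 participants for the family-wise
error calibration. These sizes are the package's declared experiment
scales; the statistical structure is unchanged by them.
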
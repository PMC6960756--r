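---
title: "Methods: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`eegaffect` implements a two-group EEG study of emotional responses to
photographs versus artwork: synthetic session generation, DEAP-format
preprocessing, windowed multi-column recognition with weighted-vote
fusion, mapping onto the Russell affect space, and per-keyword group
inference. This vignette documents the underlying models, the
assumptions they carry, the parameters that matter, and the numerical
decisions made where the design was genuinely open.

## The affect model and the keyword table

Emotions live in Russell's circumplex: valence (pleasantness) and
arousal (activation) as orthogonal axes, both scaled to [−1, 1] here.
The nine keywords — excited, happy, pleased, peaceful, calm, gloomy,
sad, fear, suspense — are anchored at fixed coordinates
(`emotion_keywords()`). The published source for this design gives the
keyword positions only pictorially, so the package's default
coordinates are conventions: hand-placed unit-square positions that
respect quadrant membership (positive valence: excited, happy, pleased,
peaceful, calm; high arousal: excited, happy, fear, suspense; low
arousal: peaceful, calm, gloomy, sad). Every function that consumes the
table accepts a user-supplied replacement. `map_to_keyword()` is
plain nearest-neighbour in Euclidean distance with a deterministic
first-row tie-break.

## The session protocol and the marker algebra

A session is 32-channel EEG in a standard 10/20 montage: 3 s baseline,
then eighteen 60 s playbacks each followed by a 5 s gap. Marker codes
delimit the protocol — code 1 at the baseline start, code 2n / 2n+1 at
the start/end of playback n, code 2·18+2 = 38 at the end of the
recording. Marker `sample_index` values are 0-based offsets at the
session's current rate (so a 3000 ms baseline at 500 Hz puts code 2 at
sample 1500); the final marker sits on the last recorded sample. The
native amplifier rate is configurable and defaults to 500 Hz — typical
for the amplifier class used in such studies, and deliberately above
128 Hz so that the downsampling stage performs real work.

Each subject's schedule covers all nine keywords in both media
(18 clips); the analysis later keeps the clips of the subject's own
group medium, giving one score per keyword per subject. If duplicate
clips of a keyword reach `assemble_responses()` they are averaged with
a warning; a missing keyword is an error naming the subject and
keyword.

## What the synthetic EEG emulates — and what it does not

Each segment (baseline, clip, gap) is a stationary Gaussian process
synthesised in the frequency domain as the sum of:

* a 1/f background (exponent 1, 8 µV RMS by default), independent per
  channel, and
* four band-limited oscillations (theta 4–8, alpha 8–13, beta 13–30,
  gamma 30–45 Hz) with baseline RMS amplitudes of 4/6/3/1.5 µV.

Affective class structure is encoded as band-power modulation: positive
valence doubles alpha power and negative valence halves it, and arousal
does the same for beta (`default_band_powers()`). Intermediate latent
levels interpolate log-linearly, so the alpha multiplier at latent
valence v is exactly 2^v. This is the minimal EEG-plausible class
signal a convolutional recognizer can learn at desk scale; it is *not*
a claim about the physiology of valence.

A fraction of each oscillation (default `channel_correlation = 0.7`)
comes from a source shared across all 32 channels, mimicking the strong
inter-channel correlation that volume conduction produces in scalp EEG.
This parameter matters more than it looks: with fully independent
channels, pooling 32 channels makes even a 0.25 s window almost
perfectly classifiable, the recognizer's probabilities saturate, and
every trial score collapses to exactly ±1 — degenerate, zero-variance
groups. With a shared source the window-level evidence is graded,
trial scores vary continuously across subjects, and the group t-tests
are well defined.

Group effects are injected as standardized shifts: the artwork group's
latent valence (and/or arousal) is moved by `effect_size ×
response_sd` relative to the photograph group, with per-subject,
per-clip latent noise of `response_sd` (default 0.15). The same
convention drives the direct response-table generator
(`simulate_response_tables()`): per-keyword means at 0.3 × the keyword
coordinate, standard deviation 0.15, clamped to [−1, 1]. The clamp sits
more than 4.8σ from every mean, so the standardized group difference
equals the configured Cohen's d to within sampling error — the
generator's scores respect the [−1, 1] response range without
distorting effect sizes.

What the generator does **not** emulate: eye-blink and muscle
artifacts, electrode drift or pops, non-stationarity within a clip,
montage-dependent spatial topographies, and any genuine physiological
valence/arousal signature. Passing tests therefore demonstrate that the
pipeline's machinery is correct and that effects of known size survive
the whole chain — not that the recognizer would reach any particular
accuracy on real recordings.

DEAP-style training data (`simulate_deap_trials()`) reuses the same
signal model at 128 Hz with binary ±1 labels at the class extremes,
emulating the schema (32 participants × 40 trials × 32 × 7680) of the
public benchmark the recognizer design was originally trained on.
Retraining on the real, licensed DEAP download is out of scope; the
published benchmark accuracies are not reproduction targets.

## Preprocessing: contracts and numerics

The stage order is fixed and logged: downsample → band-pass → reorder →
slice → detrend.

* **Downsampling** (500 → 128 Hz): an order-8 Butterworth low-pass at
  80% of the output Nyquist, applied with exactly zero phase, followed
  by natural cubic-spline interpolation at the output sample times.
  Measured behaviour: −51 dB at 100 Hz, passband gain 1.0000 at 5 Hz.
  (`signal::resample` was evaluated and rejected: its default FIR
  leaves only ~16 dB of stopband attenuation and a ~14% passband gain
  error.)
* **Band-pass** (4–45 Hz): order-4 Butterworth. Both filters are
  applied by multiplying the signal spectrum with the filter's squared
  magnitude response — the frequency-domain equivalent of
  forward–backward filtering — in one FFT across all 32 channels. Zero
  phase means marker-aligned slicing is never shifted by group delay;
  the squared magnitude doubles the effective order, exceeding the
  20 dB contracts one octave outside the band. The circular wrap-around
  this implies is negligible for minute-long, zero-mean signals.
* **Reordering** to the published 32-channel DEAP order (Geneva
  convention) is a pure row permutation; the simulated amplifier
  reports channels in a different (front-to-back) order, so this stage
  is exercised for real.
* **Slicing** requires the complete marker protocol (codes 1…38, each
  exactly once) and fails otherwise with the offending codes named.
  Trial n is the 60 s from the code-2n sample.
* **Detrending** removes the per-channel least-squares line, leaving
  channel means at numerical zero (|mean| < 10⁻⁸ × RMS by contract,
  ~10⁻¹⁷ in practice).
* The 3 s baseline is sliced and returned but not subtracted by
  default — the source protocol records it without stating a use; an
  optional `subtract_baseline` flag performs per-channel baseline-mean
  subtraction.

## Windowing and the dataset arithmetic

A window is 32 channels × 32 consecutive samples (the
`channels_by_time` layout), preserving the spatial montage for the
convolutional columns. The published phrasing also admits folding 1024
consecutive samples of one channel into a 32 × 32 matrix; that reading
is available as `layout = "single_channel_folded"`. Stride is the free
parameter that reproduces the published per-trial counts: 33 windows at
stride 232 and 80 at stride 96 (the default), via
⌊(7680 − 32)/stride⌋ + 1. With the 22/5/5 participant split × 40
trials this yields the published dataset-size range (29,040–70,400
training windows, 6,600–16,000 for validation/test). Windows inherit
their parent trial's labels; participant-level splitting guarantees no
subject contributes windows to two splits. The published formula
"7680/(32·k) positions" (= 48 at k = 5) is arithmetically inconsistent
with the 33–80 range printed beside it; the package follows the range
and treats the formula as unexplained.

## The recognizer: columns, fusion, training schedule

The fusion rule is the core contract: k columns vote vᵢ ∈ {+1, −1}
with weight wᵢ = the column's predicted probability for its voted
class, and

v_final = Σ wᵢvᵢ / Σ wᵢ.

The fused value is a weighted mean, so min(vᵢ) ≤ v_final ≤ max(vᵢ); at
exactly 0 the class tie-breaks to +1 (documented convention); if every
weight is 0 the fusion is degenerate and signals an error. Valence and
arousal are two fully independent model instances.

The original column architecture is a DenseNet-based module whose
details live outside this design's source; the column is therefore
treated as a pluggable component with a fixed contract (32 × 32 in,
one class probability out). The package's column is a small
convolutional classifier suited to the band-power class structure: a
bank of Hann-windowed sinusoidal kernels (default 24 kernels × 16 taps,
center frequencies drawn uniformly from 3–45 Hz per column seed) whose
log energies, pooled over channels and time, feed a logistic readout
trained by minibatch SGD. Distinct per-column seeds give independent
filterbanks, which is what makes the vote ensemble non-trivial.

The training schedule follows the published recipe: learning rate 10⁻⁴
(configurable; the desk-scale examples use larger rates appropriate to
a logistic readout), decreased ×0.1 when the validation error stops
decreasing — the plateau is operationalised as `patience = 3` epochs
without improvement, and training stops at `max_epochs` or after
repeated decays bring no gain. Batch size 100. The published "weight
decay 0.5" is ambiguous — 0.5 is implausibly large for an L2
coefficient — so the coefficient is exposed under three
interpretations (`off`, `l2`, `dropout`) and regularization defaults
off, with a warning for implausible L2 values. Training requires
disjoint train/validation participants and records a per-epoch,
per-column error history.

Per-trial scores are the arithmetic mean of the fused values over the
trial's windows (the window→trial aggregation is not specified in the
source design; the mean is the natural unbiased choice and keeps the
score in [−1, 1]).

## Group inference and its calibration

Per keyword and axis, the photograph and artwork groups are compared
with a two-sided Welch t-test (the source says only "t-test"; the
unequal-variance form is the safer default, and a Student flag
exists). P-values are reported raw — no multiple-testing correction by
default, matching the per-keyword reporting convention — with
Bonferroni/BH available. Tiers use strict inequalities at 0.01
and 0.05. The published per-keyword p-value table ships as a fixture
(`published_keyword_pvalues()`); it depends on the original human
recordings and is used only as input to the tiering logic. Note the
published prose for the valence row is internally inconsistent with its
own table (two "p<0.05" keywords have p < 0.01); the package follows
the printed values, and only the arousal-row summary is asserted in
tests.

`calibrate_test()` closes the loop: under a zero effect the empirical
rejection rate at α = 0.05 is 0.05 within binomial error, and with
d = 1.2 at 20 subjects/group the empirical power (~0.96) matches the
noncentral-t closed form. Rejections are pooled over the nine keywords,
which are independent draws in the generator.

## Desk-scale problem sizes

The test suite and the acceptance script run everything at sizes chosen
to keep a full check on one CPU comfortable while leaving every
contract meaningful:

* structural and filter checks use one full session (500 Hz native for
  the protocol check, 128 Hz elsewhere);
* learnability checks train k = 2 columns on 3 + 2 participants × 6
  trials of strongly separated synthetic data (9× band-power gap, with
  a band-power threshold oracle verified above 0.9 on the same
  windows);
* calibration uses 1000 null and 500 alternative replicates at the
  study size of 20 subjects per group;
* the end-to-end recovery check trains once, then simulates 20
  independent cohorts of 4 subjects per group with a valence-only shift
  of d = 2.0 — sized a priori for the reduced cohort, since d = 1.2
  has only ~15% power at n = 4 and a qualitative recovery check needs a
  detectable signal — and asks whether the per-keyword median valence
  p-value lies below the median arousal p-value for a majority of the
  nine keywords.

## Known limitations

* The recognizer column is a deliberate stand-in honoring the
  input/output contract, not a reimplementation of the original
  DenseNet module; absolute accuracies are not comparable to published
  benchmark numbers.
* The synthetic class structure is band-power-only and stationary;
  conclusions about real EEG require real recordings.
* The Welch p-value is exact only asymptotically; at n = 20 per group
  its null distribution is uniform to well within the tolerances used
  here (verified by a Kolmogorov–Smirnov check in the suite).
* EDF export quantizes to 16 bits against a per-channel symmetric
  range; round-trip error is bounded by one digital step (~0.002 µV at
  typical amplitudes).
* The trial-score aggregation (mean of fused values) saturates for
  extreme latent affect; group differences injected near the keyword
  coordinate extremes are compressed. This mirrors a genuine ceiling
  effect in bounded response scales.
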
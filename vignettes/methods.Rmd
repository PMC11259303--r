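---
title: "EEG motion-sickness detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG motion-sickness detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`vimseeg` classifies normal vs. motion-sickness EEG windows and predicts
a continuous, SSQ-scaled sickness level in sliding windows. This
vignette documents the models, every tunable that matters, the synthetic
corpus the package is validated on, and the numerical decisions taken
where the design was genuinely open. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The processing chain

An input recording is multi-channel scalp EEG in microvolts at 500 Hz,
with 10–20 channel names including the two mastoids (M1, M2). The chain
is: band-pass filter → PCA artifact removal → bilateral-mastoid
re-reference → selection of FP1, FP2, C3, C4, P3, P4, O1, O2 →
non-overlapping fixed windows (5, 10 or 12 s; 10 s default).

**Band-pass filter.** The acquisition-stage 0.1–100 Hz and
analysis-stage 0.5–50 Hz filters compose to the narrower band, so a
single 0.5–50 Hz pass is applied. An exactly zero-phase design is used:
the reflect-padded signal is multiplied in the frequency domain by a
real response that is 1 in the passband and falls to 0 over
raised-cosine transitions of width 25% of each edge frequency (0.125 Hz
at the low edge, 12.5 Hz at the high edge). A windowed time-domain FIR
with the same transitions would need ~13,000 taps at 500 Hz — longer
than a 10 s window — whereas the frequency-sampled response is exact,
linear, and zero-phase by construction; DC rejection and unit passband
gain are exact contracts tested in the suite.

**PCA artifact removal.** No published criterion accompanies
"PCA artifact removal" in this setting, so the criterion is explicit
and exposed: a principal component is zeroed iff its variance share
exceeds `var_threshold` (default 0.35) **and** the moment kurtosis of
its score series exceeds `kurt_threshold` (default 8). Large spiky
common-mode artifacts satisfy both; genuine oscillatory rhythms have
near-Gaussian scores (kurtosis ≈ 3) and are never touched. Removal can
only ever decrease total variance (tested as a property).

**Re-referencing.** Each channel minus the mean of M1 and M2; the
mastoids are dropped. If the mastoids are absent the function errors —
a silent fallback would change every downstream number invisibly. An
explicit `fallback = "average"` switches to common-average
re-referencing.

## Wavelet-packet band features

Each channel of a window is decomposed with the 8-tap Daubechies filter
(db4) to depth 8: children at level *j* arise from the level *j−1*
parent by convolution with the low-pass (even child) or high-pass (odd
child) filter and dyadic downsampling. Boundary handling is
*periodization* (odd-length nodes are extended by repeating the last
sample), chosen because it makes the analysis rows exactly orthonormal
at every even length — Parseval and perfect reconstruction then hold to
machine precision and serve as exact test oracles. The implementation
is cross-checked coefficient-for-coefficient against an independent
wavelet-packet implementation on a frozen fixture.

Because every high-pass split mirrors its branch's spectrum, natural
(filter-bank) node order is staggered with respect to frequency; the
frequency rank of natural node *i* is the inverse binary-reflected Gray
code of *i*. The permutation is verified against a tone-sweep oracle
(drive the tree with a tone at each node centre; locate the maximal
node) for depths 1–6.

A band (δ 0.5–4, θ 4–8, α 8–13, β 13–30 Hz; half-open ranges) is
reconstructed by inverting the transform over exactly the nodes whose
frequency-ordered passband centre lies in the range. At depth 8 and
500 Hz the node width is ≈0.98 Hz, so the centre rule is unambiguous
where band edges split nodes. A caveat the suite documents: db4's short
support causes spectral aliasing in deep packet trees, so a pure 10 Hz
tone keeps ≈80% (not ~100%) of its energy in the α reconstruction, with
the leaked remainder in mirror-image nodes; α still dominates every
other band by an order of magnitude. Sharper wavelets would reduce the
leakage but db4 at depth 8 is the configuration of record.

**Feature frames.** Per channel: the original signal plus the four band
reconstructions → 5 streams; 8 channels → 40 streams. Streams are
pooled to 10 frames/s by the RMS over consecutive non-overlapping
blocks. RMS (an amplitude envelope) rather than a plain mean is
deliberate: the mean of an oscillation over a 100 ms block is ≈0 for
everything above ~5 Hz and would erase precisely the band information
the decomposition produced. Pooling bounds sequence length (≤120 steps
for 12 s windows) so CPU training of the recurrent models stays in
minutes; the rate is exposed as `frames_per_s`. Streams are z-scored
with training-set statistics stored in the model — the sigmoid/tanh
network needs standardized inputs and applying stored statistics at
prediction time avoids leakage.

## The GRU models

The recurrent cell is

$$z_t = \sigma(W_z[h_{t-1},x_t]),\quad r_t = \sigma(W_r[h_{t-1},x_t]),$$
$$\tilde h_t = \tanh(W[r_t \odot h_{t-1}, x_t]),\quad
  h_t = (1-z_t)\odot h_{t-1} + z_t\odot \tilde h_t,$$

a convex combination of the previous state and the candidate. The
"Dense 40" input layer is read as a *time-distributed* 40-unit ReLU
transform applied per frame before the GRU — the only reading
consistent with a recurrent layer following it, 40 matching the
8 × 5 stream layout. The GRU consumes the frame sequence and passes its
final hidden state (width 32) to the dense head:

* classifier head 16-ReLU → 8-ReLU → 1-sigmoid, binary cross-entropy
  (probabilities clipped at 1e-7);
* predictor head 32 → 16 → 16 → 8 (ReLU) → 1-sigmoid, squared error
  against SSQ totals normalized by the scale maximum 235.62.

The printed cell equations carry no bias terms; the implementation
includes biases (standard practice) and the verification suite tests
the bias-free configuration against the equations directly — a
hand-rolled scalar recursion (1e-10) and the compiled training-path
forward (1e-6).

**Training.** ADAM with lr 5e-5, β₁ 0.9, β₂ 0.999, batch 4, 50 epochs,
and weight decay 1e-8 applied decoupled at each step. Forward/backward
(full backpropagation through time) and the update loop are compiled
(RcppArmadillo); gradients are verified against central finite
differences. All randomness — Glorot initialization and per-epoch batch
order — is drawn from R's RNG under the configured seed, so identical
`(data, config, seed)` reproduce identical weights bit-for-bit.

**Split.** 70/15/15 train/validation/test grouped by subject; a split
within subjects would leak subject-specific spectra and overstate
accuracy.

**The deviation operator.** The predictor consumes
$E_t = |x_t - R(x_t)|$, the elementwise deviation of the standardized
frame sequence from a resting-state reference. $R$ is implemented as
the subject's mean feature frame over normal-state training epochs,
broadcast over time — the simplest operator that captures "difference
from rest"; it is exposed behind a baseline argument so that, e.g., an
autoencoder reconstruction could be swapped in. For subjects unseen in
training, the pooled mean of all training-subject baselines is used.
Normal-state epochs are included in predictor training with target 0,
anchoring the resting level.

**Sliding-window prediction.** Windows of the model's width advance by
`stride_s`; each prediction is timestamped at the *window end*
(real-time convention). For onset localization, `detect_onset()`
corrects the largest smoothed increase by the window's group delay
(`window_s / 2`): a causal window first reflects a state change when
the change passes its centre. With 10 s windows this recovers the
simulated 56 s onset to well within ±10 s across seeds.

## The synthetic corpus

No recordings are published for this task, so the generator is the
canonical test input, emulating the qualitative regional pattern
reported for VIMS: broadband (δ/θ/α/β) amplitude increase over frontal
and temporal cortex; α decrease with β increase over central and
occipital cortex; parietal like central/occipital except without the β
increase. Each non-mastoid channel is a sum over bands of three
random-frequency, random-phase tones (total band power equal to a
single tone at the tabled amplitude) over 1/f ("pink", 2 µV) plus white
(1 µV) Gaussian noise; mastoids carry noise only so re-referencing is
exercised. Default amplitudes are 3–10 µV — realistic scalp-EEG rhythm
magnitudes. Severity varies across videos (ramp 0.45–0.95) and subjects
(Gaussian jitter, sd 0.08, clamped to [0.35, 1]) and interpolates the
normal-to-sickness amplitude tables; the SSQ response is drawn at that
severity (binomial items whose mean rises with the latent level), and
transition recordings blend the two state signals along a logistic ramp
with half-maximum at 56 s and slope 0.25 s⁻¹.

What the generator does *not* emulate: volume conduction and realistic
cross-channel covariance, eye/EMG artifacts (beyond the rank-1 injector
used in preprocessing tests), non-stationary background spectra, and
inter-subject spectral idiosyncrasy. Passing end-to-end tests therefore
demonstrates that the pipeline recovers the structure this model
encodes — separable band-power contrasts — not that it attains any
particular accuracy on human EEG.

## Problem sizes and numerical choices

The end-to-end runs (test suite and `scripts/acceptance.R`) use a
corpus of 9 subjects × 6 videos × 100 s per state — 1080 ten-second
epochs, ≈1000, keeping a full 50-epoch training run on one CPU to a few
minutes — while the generator's *defaults* remain the study shape
(25 subjects × 20 videos × 120 s). Other numerical choices:

* probability clipping 1e-7 in the cross-entropy; ADAM ε 1e-8;
* Glorot-uniform initialization; biases start at 0;
* degenerate inputs: an all-zero recording passes PCA unchanged (no
  component flagged), zero-variance feature streams get sd 1 in the
  z-scoring to avoid division by zero, and empty segmentations warn
  rather than error;
* windows are half-open `[t, t + w)`, non-overlapping, 0-based; the
  trailing partial window is discarded;
* EDF is written as one data record, 16 bit, symmetric physical range,
  so the round-trip error is bounded by the quantization step.

## Known limitations

* The db4 depth-8 aliasing discussed above: band reconstructions are
  faithful to the configuration of record, not brick-wall filters.
* The within-trajectory Spearman between the predicted level and the
  latent logistic ramp saturates around ~0.75–0.8: before onset and on
  the plateau the latent varies by <0.02 while prediction noise
  dominates the ranks, so rank agreement there is essentially random
  even for a near-perfect predictor. Epoch-level recovery across
  severities (Spearman ≥ 0.9 on held-out subjects) and onset timing are
  the informative trajectory statistics; both are computed by the
  acceptance script.
* Real-data accuracies cannot be reproduced or compared: the underlying
  recordings are private. The comparator figures that would contextualize
  them are out of scope.
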
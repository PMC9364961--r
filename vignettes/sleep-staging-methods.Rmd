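---
title: "Automatic sleep staging with a parallel CNN-LSTM: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic sleep staging with a parallel CNN-LSTM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepstager)
```

## The problem

Clinical sleep scoring assigns one of five AASM stages — W (wake), N1 and
N2 (light sleep), N3 (deep sleep) and REM — to every 30-second epoch of an
overnight polysomnogram. Each stage has a characteristic
electrophysiological signature: uninterrupted alpha rhythm (8–13 Hz) and
frequent blinks in wake; rising theta (4–8 Hz) in N1; sleep spindles
(12–14 Hz) and K-complexes over a theta background in N2; high-amplitude
slow delta (0.5–2 Hz) in N3; and mixed theta with sawtooth waves (2–7 Hz)
and rapid eye movements in REM. `sleepstager` implements an automatic
stager for two-channel (EEG + EOG) epochs built from a parallel
convolutional + recurrent feature-fusion network, together with a
synthetic polysomnography generator that renders those signatures so the
entire pipeline can be exercised and tested without clinical recordings.

## The network

The classifier consumes a 300 × 2 matrix per epoch — 30 s of EEG and EOG
at the 10 Hz model rate (see *Input representation*) — through two
branches in parallel:

* an **LSTM branch**: two stacked 64-unit LSTM layers. Each cell follows
  the standard gated recurrence — forget gate
  $f_t = \sigma(W_f[h_{t-1},x_t]+b_f)$, input gate
  $i_t = \sigma(W_i[h_{t-1},x_t]+b_i)$, candidate
  $\tilde c_t = \tanh(W_c[h_{t-1},x_t]+b_c)$, state
  $c_t = f_t \odot c_{t-1} + i_t \odot \tilde c_t$, output gate
  $o_t = \sigma(W_o[h_{t-1},x_t]+b_o)$ and hidden state
  $h_t = o_t \odot \tanh(c_t)$. The first layer emits its full 300 × 64
  hidden sequence; the branch feature is the second layer's final
  64-vector. A softmax-weighted pooling of the hidden sequence
  ($y=\sum_i \alpha_i h_i$ with $\alpha = \mathrm{softmax}(s)$) is
  implemented (`attention_pool()`) but disabled in the canonical
  configuration, which concatenates the plain final state.
* a **convolutional branch**: conv(64 filters × kernel 5) → batch
  normalization → ReLU ($f(x)=\max(0,x)$) → dropout → max-pool(3) →
  conv(32 × 5) → BN → ReLU → dropout → max-pool(3) → flatten.
  Convolutions are unpadded cross-correlations with stride 1 (output
  length $L-K+1$); pooling uses stride equal to the pool width with floor
  division — the only composition rules consistent with the canonical
  dimension trace below.

The two branch features are concatenated (64 + 992 = 1,056) and passed
through fully connected layers of 64 and 32 ReLU units (dropout 0.5) to a
five-way softmax; the predicted stage is the maximum-probability class.

```{r}
shape_trace(model_config())
```

Dropout is 0.20 after each convolution and 0.50 after each fully
connected layer. Batch normalization follows every convolution before its
activation, with batch statistics during training and running statistics
(momentum 0.1) at inference.

## Training regimen

Training is plain minibatch stochastic gradient descent (no momentum) on
categorical cross-entropy, batch size 10, initial learning rate 0.015
decaying 0.1-fold every 20 epochs
($\mathrm{lr}(e) = 0.015 \times 0.1^{\lfloor e/20 \rfloor}$), 100 epochs
canonically. Data handling follows three rules:

* **splits are by whole subject** (`split_by_subject()`), never by epoch,
  so no subject contributes to both training and evaluation and each
  subject's temporal sequence stays intact;
* **validation folds are night-level** (`validation_folds()`): the
  training nights are divided into equal folds (for example 48 nights
  into 12 folds of 4) and one fold can be reserved as the validation set;
* **class imbalance is handled per night** (`resample_epochs()`): within
  every (night, stage) group, counts above the cap (canonically 200) are
  sampled down without replacement and the minority stages W, N1, N3 and
  REM are sampled up with replacement to the cap, leaving N2 — typically
  about half of all sleep — never oversampled.

## Input representation

The canonical input contract is 300 samples × 2 channels per 30-s epoch,
i.e. a 10 Hz model rate. Generated (or imported) signals at a higher rate
are decimated by an integer factor with a zero-phase FFT low-pass at 90%
of the post-decimation Nyquist (4.5 Hz for the canonical rate), then
scaled by a fixed gain of 0.01 per microvolt so typical EEG amplitudes
(tens of microvolts) land in the unit range where the network
nonlinearities are responsive. Two consequences are worth knowing:

* rhythms above ~4.5 Hz (alpha, spindles, beta, most theta) are removed
  from the *model input*; the classifier distinguishes stages through the
  surviving low-frequency content (delta, K-complexes, the low edge of
  theta, sawtooth waves) and the EOG transients (blinks, rapid eye
  movements). The spectral analysis path (below) deliberately operates on
  the full-rate signal instead.
* amplitude information is preserved (the gain is fixed, not per-epoch
  normalization), so the high-amplitude character of N3 delta remains a
  usable feature.

## The synthetic generator

`generate_dataset()` builds whole nights: a per-night hypnogram, then one
two-channel epoch per hypnogram entry.

**Epoch synthesis.** Each stage is specified (`stage_spec()`) as a
weighted mixture of oscillatory components plus transient events.  A
component is rendered as random-phase band-limited noise spanning its
band — a more realistic rendering of an EEG rhythm than a pure tone, and
one that guarantees every epoch carries energy across the whole band —
scaled so its RMS matches a sinusoid with the drawn peak amplitude
(uniform in the component's amplitude range). Events are injected at
Poisson counts: Gaussian-envelope spindle bursts (12–14 Hz, 0.5–1.5 s),
biphasic negative-then-positive K-complexes (0.6–1.0 s), Hann-windowed
sawtooth bursts (2–7 Hz), and derivative-of-Gaussian blink and
rapid-eye-movement pulses on the EOG. Event amplitude defaults to 1.5×
the epoch's *realized* background amplitude (the weighted mean of the
drawn component amplitudes): scaling with the realized background rather
than a fixed stage constant keeps transients proportionate in
low-amplitude epochs, which both reads physiologically and preserves the
generator's spectral contract (below). The EOG carries a 0.3× volume-
conducted copy of the EEG background plus its own events. Broadband
Gaussian noise (SD defaulting to 10% of the dominant component's mean
amplitude) is added to both channels.

The default component weights (for example N3: delta 0.85 / theta 0.15;
N2: theta 0.75 / delta 0.10 / alpha 0.15; N1 keeps alpha below half) are
chosen so that each stage's *dominant* clinical band wins the epoch
periodogram in at least 95% of epochs — the generator's spectral
contract, verified in the test suite — while respecting the stage
descriptions (alpha reduced below 50% in N1, delta "emerging" in N2,
delta dominant in N3).

**Hypnograms.** Stage proportions default to the midpoints of the
clinical ranges (N1 5–10% → 0.075, N2 44–55% → 0.495, N3 10–20% → 0.155),
REM at the low end of its printed range (0.22), W absorbing the
remainder. Runs are geometric with stated mean bout lengths (W 3, N1 3,
N2 10, N3 8, REM 8 epochs), scheduled against per-stage epoch quotas:
each new run's stage is drawn with probability proportional to remaining
quota / mean bout and its length is truncated at the remaining quota.
This makes the realized per-night stage fractions match the targets up to
rounding for every seed — a plain semi-Markov chain reproduces the
proportions only in expectation, with night-to-night scatter large enough
to defeat any fixed tolerance.

**What the generator does not emulate.** No 1/f background, no artifacts
or electrode noise, no EMG/ECG channels, no stage-transition physiology
(arousals, cycling), and stage-conditional independence across epochs.
Passing tests therefore demonstrate that the pipeline learns and scores
*statistically separable* stage signatures end-to-end — not clinical
performance on real polysomnography.

## Spectral analysis (EMD / Hilbert)

`emd()` implements standard sifting: cubic-spline envelopes through the
local maxima and minima, mean-envelope subtraction iterated until the
Cauchy criterion $\sum(h_{k-1}-h_k)^2 / \sum h_{k-1}^2 < 0.2$ *and* the
IMF property (extrema and zero-crossing counts differing by at most one)
hold, at most 50 sifts per component and 8 components by default.
Envelopes mirror two extrema at each boundary against spline end swings.
A candidate that cannot be sifted into a valid IMF — typically a
low-extrema residual trend — ends the decomposition and stays in the
residual, so every returned IMF satisfies the property and the components
always sum exactly back to the input.

`instantaneous_frequency()` forms the analytic signal by the
frequency-domain Hilbert construction and differentiates the unwrapped
phase; 5% of samples are trimmed at each edge and negative values
(unwrapping noise) are clamped to zero with a reported count.
`stage_frequency_histograms()` pools the per-sample frequencies of the
first four IMFs across a stage's epochs into 50-bin probability-density
histograms over 0–30 Hz, the clinically considered EEG range.

One structural property of EMD deserves emphasis: sifting always peels
the *highest-frequency* oscillation first, so with broadband noise
present the first one or two IMFs are noise modes regardless of how
little energy they carry, and a count-based pooled histogram shows
high-frequency mass. The delta-dominance checks in the test suite
therefore analyze the noise-free oscillatory construction; on noisy
epochs the low-frequency dominance is visible in energy, not in IMF
counts.

## Numerical choices

* The training engine (`src/engine.cpp`) works in single precision with
  batched BLAS calls; the exported primitives and the reference forward
  pass are double-precision pure R, and the two paths are cross-checked
  to ~1e-7 in the tests. Gate nonlinearities in the engine use a clamped
  rational tanh approximation (max error ~1e-7, below the accumulation
  noise of single precision) because branch-free polynomials vectorize
  where libm calls do not.
* Initialization: Glorot-uniform weights, LSTM forget-gate bias 1 (the
  standard remedy for early gradient vanishing through long sequences),
  zero-initialized softmax layer so an untrained model emits exactly
  uniform probabilities. All randomness (initialization, shuffling,
  dropout masks) derives from one integer seed; a fitted model is
  bit-reproducible on a fixed platform with single-threaded BLAS.
* Batch normalization uses epsilon 1e-5 and biased batch variance, with
  running statistics (momentum 0.1) at inference, which also makes
  inference independent across the examples of a batch.
* Division-by-zero conventions in evaluation: a never-predicted stage has
  precision 0, an absent stage recall 0, and F1 is 0 whenever
  precision + recall is 0; absent stages still enter the macro-F1 mean by
  default (configurable via `include_empty`).

## Problem sizes used in the checks

The test suite trains the canonical network on 12 synthetic subjects ×
600 epochs (10 training / 2 held-out subjects, 30 epochs, batch 10) and
asserts held-out accuracy ≥ 0.85 and macro-F1 ≥ 0.80; unit tests use a
reduced architecture (60 × 2 input, 8-unit LSTM, 8-filter convolutions)
for second-scale runtimes. The acceptance script trains the canonical
model on 10 subjects × 300 epochs for 15 epochs — chosen as the smallest
scale at which the minority stages (W at ~5.5% of epochs, N1 at ~7.5%)
accumulate enough examples to be learned, at a few minutes' runtime —
and reports held-out accuracy,
macro F1 and per-stage F1 alongside the architecture trace, EMD
diagnostics, the learning-rate schedule and the resampling cap.

## Limitations

The real-data path (EDF import with hypnogram sidecars) is format-level
only: no artifact rejection, montage handling or EDF+ annotation parsing.
The stager's reported synthetic performance does not transfer to clinical
recordings, whose stage signatures are weaker, non-stationary and
subject-dependent. Training is single-threaded CPU SGD; there is no
momentum, early stopping or hyperparameter search, matching the canonical
regimen rather than best achievable optimization practice.
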
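---
title: "Forecast-based artefact replacement in LFP recordings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecast-based artefact replacement in LFP recordings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpclean)
```

## The model and its assumptions

`lfpclean` treats artefact removal as a missing-data imputation problem
on a single channel. Three assumptions carry the whole method:

1. **Artefacts are high power.** A window whose mean-square amplitude
   exceeds what artefact-free activity ever produces is non-physiological.
   This is the labelling rule; artefacts that match normal power are out
   of reach (see Limitations).
2. **Clean activity is locally predictable.** A forecaster trained on
   artefact-free segments can extrapolate plausible activity over an
   artefact window from the samples immediately preceding it.
3. **The channel's own history is sufficient context.** Nothing is ever
   read from other channels, so the method still works for global
   artefacts or arrays in which most channels are corrupted.

The pipeline is: window the signal → label windows by power threshold →
extract artefact-free segments → train a forecaster → overwrite each run
of artefact windows with a recursive forecast → validate with horizon
RMSE, periodograms and window-power distributions.

## Windowing and labelling

Windows are contiguous, non-overlapping and left-aligned; a trailing
partial window is excluded and never labelled or replaced. Window power
is the **mean** of squared samples (mV²), not the sum, so values are
comparable across window lengths; no taper or spectral estimate is
involved. Exceedance is **strict** (`>`): a window exactly at the
threshold stays clean. That tie-break also makes the threshold derived
from a clean reference self-consistent — the loudest clean window does
not label itself.

Thresholds come in two provenances: `manual` (one value typed in, the
workflow used at 250 Hz with 1-s windows) and `derived_from_clean_epochs`
(the maximum window power over visually validated artefact-free epochs,
the workflow used at 2 kHz with 50-ms windows). One global value or one
value per channel are both supported.

Segment extraction is a greedy left-to-right scan, emitting
non-overlapping segments only; overlap policy is not fixed by the
published description, and non-overlap avoids leaking nearly identical
segments across the train/test split. When clean and artefactual
segments are extracted for the same pipeline, a single joint scan is
used, which guarantees the two families are disjoint in sample coverage.
The train/validation/test split is segment-level i.i.d. (seeded), with
`round(fraction * n)` segments for validation and test and the remainder
for training; a chronological split is a reasonable alternative we did
not adopt because the synthetic background is stationary.

## The forecasters

All three models map `input_len` past samples to `output_len` future
samples and are driven through the same `forecast()` /
`recursive_forecast()` contract.

**LSTM.** A single recurrent layer of `round(input_len / 10)` units
(clamped to at least 1 below 10 input samples) followed by a linear dense
output. The cell is the standard gated update — sigmoid forget, input
and output gates, tanh candidate — implemented both as an exported
single-step reference (`lstm_cell_step()`) and as a batched layer; the
two are tested against each other.

**CNN-LSTM.** The 16-layer stack: sequence input, sequence folding, five
convolutions (kernel 5, 32 filters) at dilations 1, 2, 4, 8 and 16 with
batch normalisation and ELU, average pooling of size 1 and stride 5,
sequence unfolding with flattening, GRU(128), LSTM(64), dropout 0.25,
LSTM(32), dropout 0.25 and a linear regression output. Two realisation
choices were open and are resolved as follows:

* The 2-D convolutions over folded sequences are realised as **causal
  dilated 1-D convolutions along time** (left zero-padding of
  `(k-1)·d` samples), so no future sample can leak into a forecast; the
  fold/unfold layers are pass-throughs in this realisation. The input
  must be at least 80 samples so the dilation-16 kernel fits.
* "Average pooling, size 1, stride 5" is stride-5 temporal subsampling.
  We keep the **last** sample of each stride block (output length
  `floor(T/5)`), which preserves causality at the block boundary.

**ARMAX.** The linear baseline `A(q) y_t = Σ B_i(q) x_ti + C(q) e(t)` in
the standard backshift convention (`A(q) = 1 + a_1 q⁻¹ + …`, so an AR(1)
process `y_t = 0.9 y_{t-1} + e_t` has `a_1 = -0.9`). Estimation is
ordinary least squares for pure AR(X), and Hannan–Rissanen two-stage
least squares (long-AR residuals, then lagged-regression, iterated twice
with model-based residuals) when a moving-average part is present.
`orders = "auto"` selects `n_a ∈ 1..4`, `n_c ∈ 0..2` by BIC. A fitted
model whose AR roots are not all outside the unit circle is flagged
unstable with a warning. With no reference channel the exogenous part is
empty (`k = 0`) and the model is ARMA; exogenous inputs are supported
but unused by default, since what the reference input should be for a
single-channel recording is undefined. Multi-step forecasts set future
innovations to their zero mean and reconstruct in-sample innovations by
direct filtering with zero initial conditions.

## Training

* **Loss.** The reported loss is the half-mean-squared error per time
  step, `(1/2S) Σ_i Σ_j (x_ij - x̂_ij)²`, *not* normalised by the number
  of examples; `half_mse_loss()` implements it verbatim and the recorded
  history uses it. For the optimiser update the gradient of the
  per-example mean is used instead (divide by batch size), so the
  learning rate means the same thing at any batch size.
* **Optimiser.** Adam with initial learning rate 1e-4 and first-moment
  decay 0.9 (the published "momentum" figure is interpreted as Adam's
  β₁), β₂ = 0.999, ε = 1e-8. Batch size defaults to 128 (the published
  small-corpus setting; 516 is the large-corpus figure and remains
  configurable as printed).
* **Normalisation.** Inputs and targets are z-scored with the training
  set's pooled mean and standard deviation; the statistics are stored in
  the model and `forecast()` de-normalises back to mV. A zero training
  standard deviation falls back to 1.
* **Initialisation.** Glorot-uniform weights, zero biases, except the
  LSTM forget-gate bias which starts at 1 so early training does not
  erase the cell state. Weights are (re-)initialised from the master
  seed at the start of `train_forecaster()`; the same seed also drives
  batch shuffling and dropout, making a run bit-reproducible on one
  thread.
* **Early stopping** on validation loss with patience 10 validation
  checks (the published workflow stops early by inspection; a patience
  value is our choice), restoring the best weights. A non-finite loss
  aborts with an error naming the epoch.
* **Examples** are cut from clean segments as non-overlapping
  `input_len + output_len` chunks.

## Replacement

Replacement is per-channel and hard: forecast samples overwrite artefact
windows at window boundaries with no cross-fade, matching the direct
substitution the method describes. Consecutive artefact windows form a
run and are replaced by **one** recursive forecast whose context is the
`input_len` samples immediately before the run in the *working* signal —
previously replaced windows therefore contribute their forecast values
to later contexts, and partial contexts always prefer true samples from
artefact-free windows. An artefact run starting before `input_len`
samples of context exist is logged unreplaceable and left untouched. An
optional `max_run` warning flags runs long enough that compounding
recursive error may drift; substitution still proceeds because a drifted
stationary forecast is still preferable to a high-power artefact for
power-based downstream analyses.

## Evaluation

`rmse()` is the published horizon RMSE with denominator `N` (number of
test examples), so its value grows like `sqrt(S)` with the horizon;
`rmse_per_point()` divides by `sqrt(S)` for cross-horizon comparison.
Fixed horizons (200 samples at 2 kHz, 250 samples at 250 Hz) make
input/output grids comparable. The periodogram is the plain
rectangular-window estimate, scaled so one-sided linear bins sum to the
signal's mean square (Parseval); dB values floor at −300 so constant
signals stay finite. Violin plots are summarised as 5/25/50/75/95%
quantiles of per-segment mean-square power. Wall-clock time per forecast
is reported for information only and never asserted, being
hardware-dependent.

## The synthetic generator

`synth_spec()` emulates the structure of the real recordings, not their
physiology: a zero-mean stationary AR(2) background with a pole
resonance (default 8 Hz, modulus 0.97, marginal SD 0.05 mV — the
amplitude scale of clean activity after artefact removal in the
published example traces) plus sparse high-power events placed by a
seeded Bernoulli-per-window process. Event kinds cover the described
phenomenology — high-amplitude transients, high-frequency bursts,
baseline jumps — with amplitude multipliers relative to the background
SD; a separability floor guarantees every affected window's power is at
least `m²/4` times the mean background power, so ground truth and
threshold labelling agree exactly for multipliers ≥ 10. Default study
conditions are the 250 Hz scale: 600 s, 1-s windows, 4-s segments with a
1-s clean prefix, three events per minute, giving roughly 100 training
segments — the cheapest configuration that still exercises every stage.

The fixture derives its threshold from the pre-injection baseline
realisation, the synthetic analogue of visually inspected artefact-free
epochs. What passing tests on this fixture **do not** show: performance
on real LFP spectra (1/f backgrounds with multiple rhythms), on
artefacts sharing the power range of physiological activity, on
non-stationary recordings (sleep stages, behavioural transitions), or
the published RMSE figures, which require the original data sets and
their stochastic training runs.

## Numerical choices and degenerate inputs

* Window length is `round(window_seconds × fs)` samples; window counts
  are floor division. A window longer than the recording is an error.
* Empty windows, empty groups, empty test sets, fewer than three clean
  segments, ragged text files and non-numeric cells all raise typed,
  located errors rather than propagating NA.
* The binary matrix container and the result bundle (uncompressed RDS
  with a schema version) round-trip byte-identically; loading a bundle
  with a different schema version is an explicit error, and a bundle
  without model weights loads with the model marked untrained.
* MATLAB support covers Level 4 (v4) numeric matrices only — a
  20-byte header plus column-major doubles — because that subset is
  well-defined and self-contained; v5/v7 files are rejected with a
  message suggesting conversion.
* ARMA innovation recursion uses zero initial conditions; contexts
  shorter than `10 × (n_a + n_b + n_c)` are rejected.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run at desk scale, chosen so the
full pipeline (600-s fixture, 25-unit LSTM, ≤ 50 epochs, batch 128)
completes in well under a minute while still containing ~100 training
segments and ~25 artefact windows. Unit tests use 2-minute backgrounds
and models of 5–25 hidden units. The CNN-LSTM is trained only at toy
scale in tests (100-sample inputs, 2 epochs); its structure, causality,
gradients and end-to-end trainability are verified, but no claim is made
about its desk-scale accuracy relative to the LSTM.

## Known limitations

* Windows whose power stays below threshold are never touched, even when
  neighbouring windows are artefactual; segments with high-power
  surroundings can therefore retain elevated total power.
* Long artefact runs are replaced by pure recursion, which decays toward
  the process mean; replaced stretches are smoother and lower-power than
  physiological activity at horizons beyond the background's correlation
  time. The window-power criterion this package validates is insensitive
  to that, but phase-sensitive analyses would not be.
* The first `input_len` samples of a recording cannot be repaired (no
  context).
* Thresholding assumes artefacts are high power; low-power artefacts
  (e.g. flat-lining) are invisible to the labeller.
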
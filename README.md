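# lfpclean

Channel-independent artefact replacement for chronically recorded local
field potentials (LFPs).

## The problem

Invasive LFP recordings are routinely corrupted by high-power artefacts
from instrumental and physiological sources. Most removal techniques —
regression on a reference channel, adaptive filtering, inter-channel
interpolation, blind source separation — lean on *other* channels of the
array, and fail when a global artefact hits every channel at once or when
the corrupted channels outnumber the clean ones. Simply discarding the
affected epochs leaves discontinuities that break downstream analyses.

`lfpclean` implements the alternative: detect artefactual windows by a
per-channel power threshold, train a sequence forecaster on the channel's
own artefact-free history, and overwrite each artefact window with a
recursively generated forecast, so the cleaned signal preserves the
temporal and spectral continuity of physiological activity. No other
channel is ever consulted.

## The method

**Labelling.** The signal is tiled with contiguous, non-overlapping
windows (50 ms or 1 s, depending on sampling rate). A window with
mean-square power `(1/L) Σ s_i²` strictly above the channel threshold —
either set manually or derived as the maximum window power of
artefact-free reference epochs — is labelled artefactual.

**Forecasting.** Three models share one contract (`input_len` past
samples → `output_len` future samples):

* a single-hidden-layer **LSTM** with `round(input_len/10)` units
  (gates `f_t, i_t, c̃_t, o_t` with the standard sigmoid/tanh cell
  update) and a linear output layer;
* a 16-layer **CNN-LSTM**: causal dilated convolutions (kernel 5,
  32 filters, dilations 1–16) with batch-norm/ELU, stride-5 temporal
  pooling, then GRU(128) → LSTM(64) → LSTM(32) with dropout 0.25 and a
  regression output;
* an **ARMAX/ARMA** baseline `A(q) y_t = Σ B_i(q) x_ti + C(q) e(t)`,
  fitted by Hannan–Rissanen least squares, with BIC order selection.

Networks are trained with Adam (learning rate 1e-4, first-moment decay
0.9) on z-scored artefact-free segments split 80/10/10 into
train/validation/test, minimising the half-mean-squared error per time
step, `loss = (1/2S) Σ_i Σ_j (x_ij − x̂_ij)²`.

**Replacement.** Each run of consecutive artefact windows is overwritten
by one recursive sliding-window forecast from the clean context
immediately preceding it; each forecast block feeds back into the context
for the next block, so arbitrarily long runs are handled. Artefact-free
samples pass through bit-identically.

**Evaluation.** Test-set skill is the horizon RMSE
`sqrt(Σ_i Σ_j (x_ij − x̂_ij)² / N)` over a fixed horizon (e.g. 250
samples at 250 Hz), plus periodograms and window-power distribution
summaries comparing normal, artefactual and replaced segments.

## Worked example

```r
library(lfpclean)

# simulate 2 minutes of contaminated LFP at 250 Hz
fx <- make_fixture_dataset(synth_spec(duration_s = 120, seed = 42))
fx
#> <lfp_fixture> 120 s @ 250 Hz, 9 artefact window(s); 23 clean / 6 artefactual segments
fx$threshold
#> <threshold_spec> derived_from_clean_epochs: 0.00515345 mV^2

# train the single-layer LSTM forecaster (1 s in, 1 s out)
model <- build_lstm(forecast_model_spec("lstm", input_len = 250, output_len = 250))
model
#> <forecast_model> lstm: 250 -> 250 samples, 9200 parameters (untrained)
fit <- train_forecaster(model, fx$segments, cfg = train_config(max_epochs = 20, seed = 42))

# held-out forecasting skill vs the zero-order-hold baseline
evaluate_over_horizon(fit$model, fx$segments, horizon = 250)
#> <eval_report> RMSE 0.79 over 250-sample horizon (2 examples; 0.04997 per point; 0.0055 s/forecast)
evaluate_over_horizon(zoh_model(250, 250), fx$segments, horizon = 250)
#> <eval_report> RMSE 0.9643 over 250-sample horizon (2 examples; 0.06099 per point; 0.001 s/forecast)

# replace the artefact-labelled windows
res <- replace_artefacts(fx$recording, fx$labels, fit$model)
res$log
#> <replacement_log> 9 window(s) replaced, 0 unreplaceable (context 250 samples, lstm model)
pw <- window_powers(res$recording, fx$grid)
art <- fx$labels$labels == 1
sum(pw[art] > fx$threshold$values)
#> [1] 0
```

The trained LSTM beats the hold-last-value baseline over a one-second
horizon (RMSE 0.79 vs 0.96 mV; about 0.050 vs 0.061 mV per sample), and
every one of the nine windows that exceeded the power threshold is below
it after replacement.

The same pipeline is available from a shell via the staged CLI
(`inst/cli/lfpclean`): `simulate → label → extract → train → evaluate →
replace → report`, with every stage reading and writing a single
self-describing result bundle.

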
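## Shared fixtures, generated in code and cached for the test run.

.fixture_cache <- new.env(parent = emptyenv())

## 2-minute artefact-free AR(2) background split into 1000-sample segments.
ar2_segments <- function() {
  if (is.null(.fixture_cache$ar2)) {
    spec <- synth_spec(fs = 250, duration_s = 120, sigma = 0.05,
                       events = list(), seed = 3)
    base <- generate_baseline(spec)
    .fixture_cache$ar2 <- lapply(seq_len(28), function(i) {
      base$data[1, (i - 1) * 1000 + seq_len(1000)]
    })
  }
  .fixture_cache$ar2
}

## LSTM trained once on the AR(2) background, shared by several tests.
trained_ar2_model <- function() {
  if (is.null(.fixture_cache$trained_ar2)) {
    segs <- ar2_segments()
    m <- build_lstm(forecast_model_spec("lstm", 100, 10))
    fit <- train_forecaster(m, segs[1:24], segs[25:28],
                            train_config(learning_rate = 1e-3,
                                         batch_size = 64, max_epochs = 50,
                                         patience = Inf, seed = 1))
    .fixture_cache$trained_ar2 <- fit
  }
  .fixture_cache$trained_ar2
}

## Small contaminated fixture for labelling / replacement tests.
small_fixture <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- make_fixture_dataset(
      synth_spec(duration_s = 120,
                 events = list(list(kind = "amplitude_transient",
                                    amplitude = 10, duration_s = 1,
                                    rate_per_min = 3)),
                 seed = 11))
  }
  .fixture_cache$small
}

## Recording with hand-placed labels for deterministic scan traces.
labelled_recording <- function(label_vec, window_len = 10L, fs = 100) {
  n <- length(label_vec) * window_len
  rec <- recording(matrix(seq_len(n) / n, nrow = 1L), fs = fs)
  grid <- make_windows(rec, window_len / fs)
  labels <- structure(list(
    labels = matrix(as.integer(label_vec), nrow = 1L),
    grid = grid), class = "label_array")
  list(recording = rec, grid = grid, labels = labels)
}

## Stub that records every context it is given.
recording_stub <- function(input_len, output_len, value = 7) {
  env <- new.env()
  env$contexts <- list()
  env$calls <- 0L
  m <- stub_model(function(context) {
    env$calls <- env$calls + 1L
    env$contexts[[env$calls]] <- context
    rep(value, output_len)
  }, input_len, output_len)
  m$trace <- env
  m
}
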
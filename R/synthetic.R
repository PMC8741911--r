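#' AR(2) coefficients with a spectral resonance
#'
#' Places the complex pole pair of an AR(2) process at `freq_hz` with
#' modulus `r`, giving a band-limited, 1/f-like background with a peak
#' near `freq_hz` -- a convenient stand-in for theta-band LFP activity.
#'
#' @param freq_hz Resonance frequency in Hz.
#' @param r Pole modulus in (0, 1); closer to 1 gives a sharper peak.
#' @param fs Sampling frequency in Hz.
#' @return Length-2 AR coefficient vector (regression convention:
#'   `y_t = a1 y_{t-1} + a2 y_{t-2} + e_t`).
#' @export
ar_resonance <- function(freq_hz, r = 0.97, fs = 250) {
  stopifnot(r > 0, r < 1, freq_hz > 0, freq_hz < fs / 2)
  theta <- 2 * pi * freq_hz / fs
  c(2 * r * cos(theta), -r^2)
}

#' Synthetic LFP specification
#'
#' Defines a seeded synthetic recording: a zero-mean stationary AR
#' background contaminated by sparse high-power artefact events. Defaults
#' emulate the sleep-study scale: 250 Hz sampling, 1-s label windows,
#' a 0.05 mV background with an 8 Hz resonance, and a few artefact events
#' per minute whose amplitudes dwarf the background.
#'
#' @param fs Sampling frequency (Hz).
#' @param duration_s Recording duration (s).
#' @param n_channels Number of channels.
#' @param ar AR coefficient vector of the background (regression
#'   convention); default [ar_resonance()] at 8 Hz.
#' @param sigma Marginal background standard deviation (mV).
#' @param window_seconds Label window duration used for artefact placement
#'   and ground truth (s).
#' @param events List of event descriptions, each
#'   `list(kind =, amplitude =, duration_s =, rate_per_min =)` with kind
#'   one of `"amplitude_transient"`, `"hf_burst"`, `"baseline_jump"`;
#'   `amplitude` is the multiplier applied to the background sigma.
#' @param seed Integer seed fixing the entire realisation.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(fs = 250, duration_s = 600, n_channels = 1L,
                       ar = ar_resonance(8, 0.97, fs), sigma = 0.05,
                       window_seconds = 1,
                       events = list(
                         list(kind = "amplitude_transient", amplitude = 10,
                              duration_s = 1, rate_per_min = 2),
                         list(kind = "hf_burst", amplitude = 8,
                              duration_s = 1, rate_per_min = 1)
                       ),
                       seed = 1L) {
  stopifnot(fs > 0, duration_s > 0, n_channels >= 1, sigma >= 0)
  for (ev in events) {
    stopifnot(ev$kind %in% c("amplitude_transient", "hf_burst", "baseline_jump"))
    if (ev$rate_per_min < 0) stop("event rates must be >= 0")
    if (ev$duration_s >= duration_s) {
      stop("spec error: event longer than the recording")
    }
  }
  structure(list(fs = fs, duration_s = duration_s,
                 n_channels = as.integer(n_channels), ar = ar, sigma = sigma,
                 window_seconds = window_seconds, events = events,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

## Innovation sd giving a target marginal sd for an AR process, via the
## psi-weight expansion var(y) = sigma_e^2 * sum(psi_j^2).
ar_innovation_sd <- function(ar, sigma) {
  if (length(ar) == 0L) return(sigma)
  psi <- stats::ARMAtoMA(ar = ar, ma = numeric(0), lag.max = 5000L)
  sigma / sqrt(1 + sum(psi^2))
}

#' Generate the artefact-free synthetic background
#'
#' Seeded, zero-mean, stationary AR realisation per channel, scaled to the
#' requested marginal standard deviation.
#'
#' @param spec A [synth_spec()].
#' @return An [recording()] object (`spec$n_channels` x
#'   `fs * duration_s` samples, mV).
#' @export
generate_baseline <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (length(spec$ar) > 0 && !all(Mod(polyroot(c(1, -spec$ar))) > 1)) {
    stop("stability error: AR coefficients are not stationary")
  }
  n <- as.integer(round(spec$fs * spec$duration_s))
  sd_e <- ar_innovation_sd(spec$ar, spec$sigma)
  data <- withr::with_seed(spec$seed, {
    m <- matrix(0, spec$n_channels, n)
    for (ch in seq_len(spec$n_channels)) {
      if (spec$sigma == 0) next
      m[ch, ] <- as.numeric(stats::arima.sim(
        model = if (length(spec$ar)) list(ar = spec$ar) else list(),
        n = n, sd = sd_e))
    }
    m
  })
  recording(data, fs = spec$fs)
}

event_waveform <- function(kind, amplitude_mv, n_samp, fs) {
  tt <- seq_len(n_samp) / fs
  switch(kind,
    amplitude_transient = amplitude_mv * sin(2 * pi * 12 * tt),
    hf_burst = amplitude_mv * sin(2 * pi * 0.35 * fs * tt),
    baseline_jump = rep(amplitude_mv, n_samp),
    stop("unknown event kind: ", kind)
  )
}

#' Inject ground-truth artefact events
#'
#' Places events by a seeded Bernoulli-per-window process: each complete
#' window draws each event kind with probability
#' `rate_per_min * window_seconds / 60`; a drawn event starts at the
#' window boundary and spans `ceiling(duration / window)` windows. Event
#' amplitudes are `amplitude * sigma` mV and are scaled up if needed so
#' every affected window's power is at least `amplitude^2 / 4` times the
#' background's mean power, guaranteeing separability from clean activity.
#'
#' @param recording A [generate_baseline()] recording (or any recording
#'   matching the spec geometry).
#' @param spec The [synth_spec()] describing the events.
#' @return List with `recording` (contaminated copy) and `truth`, a
#'   ground-truth `label_array` marking every affected window.
#' @export
inject_artefacts <- function(recording, spec) {
  stopifnot(inherits(recording, "lfp_recording"), inherits(spec, "synth_spec"))
  grid <- make_windows(recording, spec$window_seconds)
  truth <- matrix(0L, n_channels(recording), grid$n_windows)
  rates <- vapply(spec$events, function(e) e$rate_per_min, numeric(1L))
  if (length(spec$events) == 0L || all(rates == 0)) {
    return(list(recording = recording,
                truth = structure(list(labels = truth, grid = grid),
                                  class = "label_array")))
  }
  L <- grid$window_len
  out <- recording
  mean_bg_power <- mean(recording$data^2)
  withr::with_seed(spec$seed + 7919L, {
    for (ch in seq_len(n_channels(recording))) {
      for (ev in spec$events) {
        if (ev$rate_per_min <= 0) next
        p_win <- min(1, ev$rate_per_min * spec$window_seconds / 60)
        hits <- which(stats::runif(grid$n_windows) < p_win)
        n_ev_win <- max(1L, as.integer(ceiling(ev$duration_s / spec$window_seconds)))
        for (w in hits) {
          w_end <- min(w + n_ev_win - 1L, grid$n_windows)
          i0 <- (w - 1L) * L + 1L
          i1 <- w_end * L
          wav <- event_waveform(ev$kind, ev$amplitude * spec$sigma,
                                i1 - i0 + 1L, recording$fs)
          seg <- out$data[ch, i0:i1] + wav
          ## enforce the separability floor window by window
          floor_p <- ev$amplitude^2 / 4 * mean_bg_power
          for (wk in w:w_end) {
            rel <- (wk - w) * L + seq_len(L)
            guard <- 0L
            while (mean(seg[rel]^2) < floor_p && guard < 50L) {
              wav[rel] <- wav[rel] * 1.2
              seg[rel] <- out$data[ch, i0 + rel - 1L] + wav[rel]
              guard <- guard + 1L
            }
          }
          out$data[ch, i0:i1] <- seg
          truth[ch, w:w_end] <- 1L
        }
      }
    }
  })
  list(recording = out,
       truth = structure(list(labels = truth, grid = grid),
                         class = "label_array"))
}

#' Build the full seeded fixture data set
#'
#' Runs generate -> inject -> threshold -> label -> joint segment
#' extraction -> split under one master seed. The threshold is derived
#' from the pre-injection baseline (the synthetic analogue of visually
#' inspected artefact-free epochs), which with strict exceedance gives
#' exact ground-truth agreement: injected windows are the only ones
#' labelled.
#'
#' @param spec A [synth_spec()].
#' @param segment_seconds Clean/artefactual segment duration (s).
#' @param clean_prefix_seconds Artefact-free prefix required of
#'   artefactual segments (s).
#' @param fractions Train/val/test fractions for [split_segments()].
#' @return An object of class `lfp_fixture`: `recording` (contaminated),
#'   `clean_recording`, `truth`, `labels`, `threshold`, `grid`, `segments`
#'   (split `segment_set`) and the `spec`.
#' @export
make_fixture_dataset <- function(spec, segment_seconds = 4,
                                 clean_prefix_seconds = 1,
                                 fractions = c(0.8, 0.1, 0.1)) {
  stopifnot(inherits(spec, "synth_spec"))
  clean <- generate_baseline(spec)
  inj <- inject_artefacts(clean, spec)
  grid <- inj$truth$grid
  thr <- derive_threshold(
    lapply(seq_len(n_channels(clean)), function(ch) clean$data[ch, ]),
    grid)
  labels <- label_windows(inj$recording, grid, thr)
  segs <- extract_segments(inj$recording, labels, segment_seconds,
                           clean_prefix_seconds)
  if (length(segs$clean) < 3L) {
    stop("insufficient data: too few clean segments for a split; increase duration or lower event rates")
  }
  segs <- split_segments(segs, fractions, seed = spec$seed)
  structure(list(
    recording = inj$recording,
    clean_recording = clean,
    truth = inj$truth,
    labels = labels,
    threshold = thr,
    grid = grid,
    segments = segs,
    spec = spec
  ), class = "lfp_fixture")
}

#' @export
print.lfp_fixture <- function(x, ...) {
  cat(sprintf(
    "<lfp_fixture> %.0f s @ %g Hz, %d artefact window(s); %d clean / %d artefactual segments\n",
    x$spec$duration_s, x$spec$fs, sum(x$truth$labels),
    length(x$segments$clean), length(x$segments$artefactual)))
  invisible(x)
}
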
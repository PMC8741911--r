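#' LFP recording object
#'
#' Container for a multi-channel voltage time series. Amplitudes are stored
#' in millivolts after the load-time `scale` factor has been applied, so a
#' file recorded in volts is read with `scale = 1000`.
#'
#' @param data Numeric matrix of voltage samples, channels in rows and
#'   samples in columns. A plain numeric vector is treated as one channel.
#' @param fs Sampling frequency in Hz (positive scalar).
#' @param scale Multiplicative amplitude factor applied on load
#'   (dimensionless, finite and non-zero). `scale = 1` is the identity.
#' @param channel_ids Optional character vector of channel labels, one per
#'   row of `data`. Defaults to `"ch1"`, `"ch2"`, ...
#'
#' @return An object of class `lfp_recording` with elements `data` (the
#'   scaled channels x samples matrix), `fs`, `scale` and `channel_ids`.
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(400), nrow = 2), fs = 200)
#' n_channels(rec)
recording <- function(data, fs, scale = 1, channel_ids = NULL) {
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, nrow = 1L)
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix (channels x samples)")
  }
  if (!all(is.finite(data))) stop("all samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a positive finite scalar (Hz)")
  }
  check_scale(scale)
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_ids) != nrow(data)) {
    stop("`channel_ids` must have one entry per channel")
  }
  out <- list(
    data = data * scale,
    fs = as.numeric(fs),
    scale = as.numeric(scale),
    channel_ids = as.character(channel_ids)
  )
  class(out) <- "lfp_recording"
  out
}

check_scale <- function(scale) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale == 0) {
    stop("`scale` must be a finite, non-zero scalar")
  }
  invisible(scale)
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf(
    "<lfp_recording> %d channel(s) x %d samples @ %g Hz (%.2f s)\n",
    n_channels(x), n_samples(x), x$fs, n_samples(x) / x$fs
  ))
  invisible(x)
}

#' Number of channels / samples in a recording
#'
#' @param recording An [recording()] object.
#' @return Integer count.
#' @export
n_channels <- function(recording) nrow(recording$data)

#' @rdname n_channels
#' @export
n_samples <- function(recording) ncol(recording$data)

#' Non-overlapping window grid over a recording
#'
#' Divides a recording into contiguous, left-aligned, non-overlapping
#' windows of a fixed duration. A trailing partial window is excluded and
#' never labelled or replaced.
#'
#' @param recording An [recording()] object.
#' @param window_seconds Window duration in seconds; `window_seconds * fs`
#'   must be at least one sample.
#'
#' @return An object of class `window_grid` with elements `window_len`
#'   (samples per window, `round(window_seconds * fs)`), `n_windows`
#'   (complete windows, floor division) and `fs`.
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(240), nrow = 1), fs = 2000)
#' make_windows(rec, 0.05) # 100-sample windows, 2 of them
make_windows <- function(recording, window_seconds) {
  stopifnot(inherits(recording, "lfp_recording"))
  if (!is.numeric(window_seconds) || length(window_seconds) != 1L ||
      !is.finite(window_seconds) || window_seconds * recording$fs < 1) {
    stop("invalid window: `window_seconds * fs` must be >= 1 sample")
  }
  window_len <- as.integer(round(window_seconds * recording$fs))
  if (window_len > n_samples(recording)) {
    stop(sprintf(
      "invalid window: window of %d samples is longer than the recording (%d samples)",
      window_len, n_samples(recording)
    ))
  }
  grid <- list(
    window_len = window_len,
    n_windows = n_samples(recording) %/% window_len,
    fs = recording$fs
  )
  class(grid) <- "window_grid"
  grid
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf(
    "<window_grid> %d windows of %d samples (%.4g s @ %g Hz)\n",
    x$n_windows, x$window_len, x$window_len / x$fs, x$fs
  ))
  invisible(x)
}

#' Sample indices of one window
#'
#' @param grid A [make_windows()] grid.
#' @param w Window index (1-based).
#' @return Integer vector of sample indices covered by window `w`.
#' @export
window_samples <- function(grid, w) {
  stopifnot(inherits(grid, "window_grid"), w >= 1, w <= grid$n_windows)
  ((w - 1L) * grid$window_len + 1L):(w * grid$window_len)
}

#' Mean-square power of a sample window
#'
#' Power is defined as the mean of squared amplitudes, `(1/L) * sum(s^2)`,
#' in mV^2. The mean (not the sum) keeps values comparable across window
#' lengths; no taper or spectral estimate is involved.
#'
#' @param samples Non-empty finite numeric vector (mV).
#' @return Non-negative scalar power in mV^2; zero iff all samples are zero.
#' @export
#' @examples
#' window_power(c(1, -1, 1, -1)) # 1
window_power <- function(samples) {
  if (length(samples) == 0L) stop("invalid input: empty window")
  if (!is.numeric(samples) || !all(is.finite(samples))) {
    stop("invalid input: samples must be finite numeric")
  }
  mean(samples^2)
}

#' Per-window power matrix of a recording
#'
#' @param recording An [recording()] object.
#' @param grid A [make_windows()] grid on that recording.
#' @return Numeric matrix (channels x windows) of mean-square powers (mV^2).
#' @export
window_powers <- function(recording, grid) {
  stopifnot(inherits(recording, "lfp_recording"), inherits(grid, "window_grid"))
  check_grid_match(recording, grid)
  L <- grid$window_len
  nw <- grid$n_windows
  out <- matrix(NA_real_, n_channels(recording), nw,
                dimnames = list(recording$channel_ids, NULL))
  for (ch in seq_len(n_channels(recording))) {
    x <- recording$data[ch, seq_len(nw * L)]
    dim(x) <- c(L, nw)
    out[ch, ] <- colMeans(x^2)
  }
  out
}

check_grid_match <- function(recording, grid) {
  if (grid$fs != recording$fs) {
    stop("dimension error: grid and recording sampling frequencies differ")
  }
  if (grid$n_windows * grid$window_len > n_samples(recording)) {
    stop("dimension error: grid does not fit the recording")
  }
  invisible(TRUE)
}

#' Rescale the amplitudes of a recording
#'
#' @param recording An [recording()] object.
#' @param factor Finite, non-zero multiplicative factor.
#' @return A new `lfp_recording` with every sample multiplied by `factor`;
#'   the sampling frequency is unchanged and the stored `scale` is updated
#'   to the cumulative factor applied since load.
#' @export
scale_recording <- function(recording, factor) {
  stopifnot(inherits(recording, "lfp_recording"))
  check_scale(factor)
  recording$data <- recording$data * factor
  recording$scale <- recording$scale * factor
  recording
}
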
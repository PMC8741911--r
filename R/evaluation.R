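#' Root mean squared forecast error over a horizon
#'
#' `rmse()` is the published definition: with forecasts and truth as
#' N x S matrices (N examples, S samples of horizon),
#' `sqrt(sum((x - xhat)^2) / N)` -- note the denominator is the number of
#' examples N, not N * S, so the value grows like `sqrt(S)` for i.i.d.
#' residuals. `rmse_per_point()` divides by `sqrt(S)` as well, giving the
#' horizon-invariant per-sample variant for comparisons across horizons.
#'
#' @param forecasts,truth Equal-shaped finite numeric matrices (N x S); a
#'   vector is treated as one example.
#' @return Non-negative scalar (mV); zero iff all forecasts are exact.
#' @export
#' @examples
#' rmse(matrix(c(3, 4)), matrix(c(0, 0))) # sqrt(25 / 2)
rmse <- function(forecasts, truth) {
  if (is.vector(forecasts)) forecasts <- matrix(forecasts, nrow = 1L)
  if (is.vector(truth)) truth <- matrix(truth, nrow = 1L)
  if (!all(dim(forecasts) == dim(truth))) {
    stop("dimension error: forecasts and truth must have the same shape")
  }
  if (!all(is.finite(forecasts)) || !all(is.finite(truth))) {
    stop("inputs must be finite")
  }
  sqrt(sum((forecasts - truth)^2) / nrow(forecasts))
}

#' @rdname rmse
#' @export
rmse_per_point <- function(forecasts, truth) {
  if (is.vector(forecasts)) forecasts <- matrix(forecasts, nrow = 1L)
  rmse(forecasts, truth) / sqrt(ncol(forecasts))
}

#' Half-mean-squared forecast loss
#'
#' The training loss as reported: `(1 / (2 * S)) * sum((x - xhat)^2)` over
#' all N examples and S output samples -- a half MSE per time step, not
#' normalised by N.
#'
#' @param pred,truth Equal-shaped numeric matrices, examples in rows and
#'   the S output samples in columns; vectors are treated as one example.
#' @return Non-negative scalar.
#' @export
half_mse_loss <- function(pred, truth) {
  if (is.vector(pred)) pred <- matrix(pred, nrow = 1L)
  if (is.vector(truth)) truth <- matrix(truth, nrow = 1L)
  if (!all(dim(pred) == dim(truth))) {
    stop("dimension error: pred and truth must have the same shape")
  }
  sum((pred - truth)^2) / (2 * ncol(pred))
}

#' Evaluate a forecaster over a fixed horizon of unseen data
#'
#' For each test segment, a recursive forecast is generated from the first
#' `input_len` samples over `horizon` samples and compared to the true
#' continuation with [rmse()]. Using one fixed horizon for every model
#' makes input/output grids comparable (e.g. 0.1 s = 200 samples at 2 kHz,
#' 1 s = 250 samples at 250 Hz).
#'
#' @param model A forecaster usable with [recursive_forecast()].
#' @param test A list of sample vectors or a [split_segments()]
#'   `segment_set` (its test split is used). Each segment must be at least
#'   `input_len + horizon` samples long.
#' @param horizon Evaluation horizon in samples.
#' @return An `eval_report`: `rmse`, `rmse_per_point`, `horizon`,
#'   `n_examples`, per-example squared-error sums and the informational
#'   wall time per forecast in seconds.
#' @export
evaluate_over_horizon <- function(model, test, horizon) {
  segs <- resolve_split(test, "test")
  I <- model$spec$input_len
  horizon <- as.integer(horizon)
  segs <- Filter(function(s) length(s) >= I + horizon, segs)
  if (length(segs) == 0L) {
    stop("insufficient data: no test segment has input_len + horizon samples")
  }
  N <- length(segs)
  fc <- matrix(0, N, horizon)
  tr <- matrix(0, N, horizon)
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_len(N)) {
    s <- segs[[i]]
    fc[i, ] <- recursive_forecast(model, s[seq_len(I)], horizon)
    tr[i, ] <- s[I + seq_len(horizon)]
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  sse <- rowSums((fc - tr)^2)
  structure(list(
    rmse = sqrt(sum(sse) / N),
    rmse_per_point = sqrt(sum(sse) / N) / sqrt(horizon),
    horizon = horizon,
    n_examples = N,
    per_example_sse = sse,
    wall_time_per_forecast_s = elapsed / N
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> RMSE %.4g over %d-sample horizon (%d examples; %.4g per point; %.3g s/forecast)\n",
    x$rmse, x$horizon, x$n_examples, x$rmse_per_point,
    x$wall_time_per_forecast_s))
  invisible(x)
}

#' Periodogram of a signal
#'
#' Plain (rectangular-window) periodogram scaled so that the one-sided
#' linear power bins sum to the signal's mean-square value (Parseval).
#' Power is also reported in dB (`10 * log10`), with zero-power bins
#' floored at `db_floor` so constant signals remain finite.
#'
#' @param signal Numeric sample vector, at least 8 samples.
#' @param fs Sampling frequency in Hz.
#' @param db_floor Floor for the dB scale (default -300).
#' @return An object of class `lfp_periodogram` with `freq` (Hz, 0 to
#'   fs/2), `power` (linear, mV^2) and `power_db`.
#' @export
#' @examples
#' p <- periodogram(sin(2 * pi * 10 * seq(0, 1, by = 1 / 250)), fs = 250)
#' p$freq[which.max(p$power)] # 10 Hz
periodogram <- function(signal, fs, db_floor = -300) {
  x <- as.numeric(signal)
  n <- length(x)
  if (n < 8L) stop("signal must have at least 8 samples")
  if (!all(is.finite(x))) stop("signal must be finite")
  X <- stats::fft(x)
  half <- floor(n / 2)
  p_full <- Mod(X)^2 / n^2
  p <- p_full[seq_len(half + 1L)]
  if (n %% 2 == 0) {
    if (half >= 2) p[2:half] <- 2 * p[2:half] # Nyquist bin not doubled
  } else {
    p[2:(half + 1L)] <- 2 * p[2:(half + 1L)]
  }
  freq <- (0:half) * fs / n
  pdb <- ifelse(p > 0, 10 * log10(p), db_floor)
  pdb <- pmax(pdb, db_floor)
  structure(list(freq = freq, power = p, power_db = pdb, fs = fs, n = n),
            class = "lfp_periodogram")
}

#' @export
print.lfp_periodogram <- function(x, ...) {
  cat(sprintf("<lfp_periodogram> %d bins, 0-%.4g Hz, peak %.4g dB at %.4g Hz\n",
              length(x$freq), max(x$freq), max(x$power_db),
              x$freq[which.max(x$power)]))
  invisible(x)
}

#' Chunk-averaged periodogram
#'
#' Averages plain periodograms over consecutive non-overlapping chunks,
#' trading frequency resolution for variance reduction (Bartlett's
#' method). Used to validate spectra of long synthetic realisations.
#'
#' @inheritParams periodogram
#' @param chunk_seconds Chunk duration in seconds.
#' @return An `lfp_periodogram` with the averaged spectrum.
#' @export
averaged_periodogram <- function(signal, fs, chunk_seconds, db_floor = -300) {
  L <- as.integer(round(chunk_seconds * fs))
  n_chunks <- length(signal) %/% L
  if (n_chunks < 1L) stop("signal shorter than one chunk")
  acc <- NULL
  for (k in seq_len(n_chunks)) {
    p <- periodogram(signal[(k - 1L) * L + seq_len(L)], fs, db_floor)
    acc <- if (is.null(acc)) p$power else acc + p$power
  }
  p$power <- acc / n_chunks
  p$power_db <- pmax(ifelse(p$power > 0, 10 * log10(p$power), db_floor),
                     db_floor)
  p
}

#' Window-power distribution summaries per segment group
#'
#' Computes each segment's mean-square power and summarising quantiles
#' (5, 25, 50, 75, 95%) per group, the tabular counterpart of the
#' violin-plot comparison between normal, artefactual and replaced
#' segments.
#'
#' @param groups Named list of non-empty lists of sample vectors, e.g.
#'   `list(normal = ..., artefactual = ..., replaced = ...)`.
#' @return List of `power_summary` objects (one per group), each with
#'   `group`, per-segment `power` values (mV^2) and `quantiles`.
#' @export
power_distribution <- function(groups) {
  if (!is.list(groups) || length(groups) == 0L) {
    stop("invalid input: `groups` must be a non-empty list")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  out <- lapply(names(groups), function(nm) {
    segs <- groups[[nm]]
    if (length(segs) == 0L) {
      stop(sprintf("invalid input: group '%s' is empty", nm))
    }
    pw <- vapply(segs, window_power, numeric(1L))
    structure(list(group = nm, power = pw,
                   quantiles = stats::quantile(pw, qs, names = TRUE)),
              class = "power_summary")
  })
  names(out) <- names(groups)
  out
}

#' @export
print.power_summary <- function(x, ...) {
  cat(sprintf("<power_summary> %s: n=%d, median %.4g mV^2 (5-95%%: %.4g-%.4g)\n",
              x$group, length(x$power), x$quantiles[["50%"]],
              x$quantiles[["5%"]], x$quantiles[["95%"]]))
  invisible(x)
}
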
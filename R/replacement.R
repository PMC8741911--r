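#' Recursive sliding-window forecast
#'
#' Generates an arbitrary-length forecast by repeatedly calling
#' [forecast()]: each call's predictions are appended to the context tail,
#' the context slides forward by `output_len` samples, and the final call
#' is truncated to the remaining horizon. Exactly
#' `ceiling(horizon / output_len)` model invocations are made.
#'
#' @param model A `forecast_model` or `forecast_stub` with `input_len` /
#'   `output_len` in its spec.
#' @param context Numeric vector of exactly `input_len` past samples (mV).
#' @param horizon Total number of samples to generate (>= 1).
#' @return Numeric vector of `horizon` forecast samples.
#' @export
recursive_forecast <- function(model, context, horizon) {
  I <- model$spec$input_len
  O <- model$spec$output_len
  if (length(context) != I) {
    stop(sprintf("shape error: context must have %d samples, got %d",
                 I, length(context)))
  }
  horizon <- as.integer(horizon)
  if (horizon < 1L) stop("horizon must be >= 1")
  out <- numeric(0)
  buf <- context
  step <- 0L
  while (length(out) < horizon) {
    step <- step + 1L
    pred <- forecast(model, buf[(length(buf) - I + 1L):length(buf)])
    if (!all(is.finite(pred))) {
      stop(sprintf("propagation error: non-finite prediction at recursion step %d",
                   step))
    }
    take <- min(O, horizon - length(out))
    out <- c(out, pred[seq_len(take)])
    buf <- c(buf, pred[seq_len(take)])
  }
  out
}

#' Replace artefact-labelled windows with model forecasts
#'
#' Channel-independent in-place substitution: each run of consecutive
#' artefact-labelled windows is overwritten by one recursive forecast
#' generated from the `context_len` samples immediately preceding the run
#' in the working signal, so previously replaced windows contribute their
#' forecast values to subsequent contexts. Artefact-free samples are
#' passed through bit-identically and the output has the same length and
#' channel count as the input. Windows at the start of a recording whose
#' preceding context is unavailable are logged unreplaceable and left
#' unchanged.
#'
#' @param recording An [recording()] object.
#' @param labels A [label_windows()] result on the recording's grid.
#' @param model Forecaster whose `input_len` equals `context_len`.
#' @param context_len Context length in samples; defaults to the model's
#'   `input_len`.
#' @param max_run Optional warning threshold: artefact runs longer than
#'   this many windows are still replaced by pure recursion, but a warning
#'   notes that compounding forecast error may drift. Default unlimited.
#' @return List with `recording` (cleaned copy) and `log`, a
#'   `replacement_log` holding per-channel replaced and unreplaceable
#'   window indices, the model spec and the context length.
#' @export
replace_artefacts <- function(recording, labels, model,
                              context_len = model$spec$input_len,
                              max_run = Inf) {
  stopifnot(inherits(recording, "lfp_recording"), inherits(labels, "label_array"))
  grid <- labels$grid
  check_grid_match(recording, grid)
  if (nrow(labels$labels) != n_channels(recording)) {
    stop("dimension error: labels and recording channel counts differ")
  }
  if (context_len != model$spec$input_len) {
    stop("shape error: context_len must equal the model's input_len")
  }
  L <- grid$window_len
  cleaned <- recording
  log_ch <- vector("list", n_channels(recording))
  for (ch in seq_len(n_channels(recording))) {
    lab <- labels$labels[ch, ]
    replaced <- integer(0)
    unrep <- data.frame(window = integer(0), reason = character(0))
    w <- 1L
    while (w <= grid$n_windows) {
      if (lab[w] == 1L) {
        run_end <- w
        while (run_end < grid$n_windows && lab[run_end + 1L] == 1L) {
          run_end <- run_end + 1L
        }
        run_len <- run_end - w + 1L
        start_sample <- (w - 1L) * L + 1L
        if (start_sample - context_len < 1L) {
          unrep <- rbind(unrep, data.frame(window = w:run_end,
                                           reason = "insufficient_context"))
        } else {
          if (run_len > max_run) {
            warning(sprintf(
              "channel %d: artefact run of %d windows exceeds max_run = %s; recursive forecast may drift",
              ch, run_len, format(max_run)))
          }
          ctx <- cleaned$data[ch, (start_sample - context_len):(start_sample - 1L)]
          pred <- recursive_forecast(model, ctx, run_len * L)
          cleaned$data[ch, start_sample:(start_sample + run_len * L - 1L)] <- pred
          replaced <- c(replaced, w:run_end)
        }
        w <- run_end + 1L
      } else {
        w <- w + 1L
      }
    }
    log_ch[[ch]] <- list(replaced = replaced, unreplaceable = unrep)
  }
  log <- structure(list(
    channels = log_ch,
    model_spec = model$spec,
    context_len = as.integer(context_len)
  ), class = "replacement_log")
  list(recording = cleaned, log = log)
}

#' @export
print.replacement_log <- function(x, ...) {
  nr <- sum(vapply(x$channels, function(c) length(c$replaced) + 0, numeric(1)))
  nu <- sum(vapply(x$channels, function(c) nrow(c$unreplaceable) + 0, numeric(1)))
  cat(sprintf(
    "<replacement_log> %d window(s) replaced, %d unreplaceable (context %d samples, %s model)\n",
    nr, nu, x$context_len, x$model_spec$architecture))
  invisible(x)
}
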
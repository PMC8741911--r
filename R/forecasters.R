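#' Forecast model specification
#'
#' Describes a sequence regressor that maps a context of `input_len` past
#' samples to `output_len` future samples.
#'
#' @param architecture `"lstm"` (single recurrent hidden layer with
#'   one-tenth of the input as units), `"cnn_lstm"` (the dilated
#'   convolutional-recurrent stack, see [build_cnn_lstm()]) or `"custom"`.
#' @param input_len Context length in samples; must be at least
#'   `output_len`.
#' @param output_len Number of samples forecast per model call.
#' @param hidden_size Recurrent units for the `"lstm"` architecture;
#'   defaults to `round(input_len / 10)`, clamped to at least 1.
#' @return An object of class `forecast_model_spec`.
#' @export
forecast_model_spec <- function(architecture = c("lstm", "cnn_lstm", "custom"),
                                input_len, output_len, hidden_size = NULL) {
  architecture <- match.arg(architecture)
  input_len <- as.integer(input_len)
  output_len <- as.integer(output_len)
  if (output_len < 1L || input_len < output_len) {
    stop("require input_len >= output_len >= 1")
  }
  if (is.null(hidden_size) && architecture == "lstm") {
    if (input_len < 10L) {
      warning("input_len < 10: hidden size clamps to 1")
      hidden_size <- 1L
    } else {
      hidden_size <- as.integer(round(input_len / 10))
    }
  }
  if (!is.null(hidden_size) && hidden_size < 1L) {
    stop("hidden_size must be >= 1")
  }
  structure(list(architecture = architecture, input_len = input_len,
                 output_len = output_len,
                 hidden_size = if (is.null(hidden_size)) NA_integer_
                               else as.integer(hidden_size)),
            class = "forecast_model_spec")
}

new_forecast_model <- function(layers, spec, layer_types) {
  structure(list(
    layers = layers,
    spec = spec,
    layer_types = layer_types,
    norm = list(mean = 0, sd = 1),
    trained = FALSE
  ), class = "forecast_model")
}

#' @export
print.forecast_model <- function(x, ...) {
  cat(sprintf("<forecast_model> %s: %d -> %d samples, %d parameters%s\n",
              x$spec$architecture, x$spec$input_len, x$spec$output_len,
              n_params(x), if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

init_model <- function(model, seed = 0L) {
  withr::with_seed(seed, {
    for (l in model$layers) init_layer_params(l)
  })
  model
}

#' Build the single-hidden-layer LSTM forecaster
#'
#' Network: scalar sequence input of `input_len` steps, one LSTM layer with
#' `round(input_len / 10)` units (unless overridden), and a linear dense
#' output of `output_len` samples.
#'
#' @param spec A [forecast_model_spec()] with `architecture = "lstm"`.
#' @return An untrained `forecast_model`.
#' @export
#' @examples
#' m <- build_lstm(forecast_model_spec("lstm", input_len = 200, output_len = 10))
#' n_params(m)
build_lstm <- function(spec) {
  stopifnot(inherits(spec, "forecast_model_spec"),
            spec$architecture == "lstm")
  H <- spec$hidden_size
  layers <- list(
    layer_identity("sequence_input"),
    layer_lstm(1L, H, mode = "last"),
    layer_dense(H, spec$output_len)
  )
  model <- new_forecast_model(layers, spec,
                              c("sequence_input", "lstm", "dense"))
  init_model(model)
}

#' Build the dilated CNN-LSTM forecaster
#'
#' Sixteen-layer stack: sequence input, sequence folding, a causal
#' convolution (kernel 5, 32 filters, dilation 1), batch normalisation with
#' ELU, four further causal convolutions with ELU at dilations 2, 4, 8 and
#' 16, average pooling (size 1, stride 5, i.e. stride-5 temporal
#' subsampling), sequence unfolding with flattening, GRU(128), LSTM(64),
#' dropout 0.25, LSTM(32), dropout 0.25 and a linear regression output.
#' Convolutions are left-padded so no future sample leaks into a forecast.
#'
#' @param spec A [forecast_model_spec()] with `architecture = "cnn_lstm"`
#'   and `input_len >= 80` so the dilation-16 kernels fit.
#' @return An untrained `forecast_model`.
#' @export
build_cnn_lstm <- function(spec) {
  stopifnot(inherits(spec, "forecast_model_spec"),
            spec$architecture == "cnn_lstm")
  if (spec$input_len < 80L) {
    stop("architecture error: input too short for the dilated convolution stack (need >= 80 samples)")
  }
  layers <- list(
    layer_identity("sequence_input"),
    layer_identity("fold"),
    layer_conv1d(1L, 32L, kernel = 5L, dilation = 1L, elu = FALSE),
    layer_batchnorm_elu(32L),
    layer_conv1d(32L, 32L, kernel = 5L, dilation = 2L, elu = TRUE),
    layer_conv1d(32L, 32L, kernel = 5L, dilation = 4L, elu = TRUE),
    layer_conv1d(32L, 32L, kernel = 5L, dilation = 8L, elu = TRUE),
    layer_conv1d(32L, 32L, kernel = 5L, dilation = 16L, elu = TRUE),
    layer_avgpool(stride = 5L),
    layer_identity("unfold_flatten"),
    layer_gru(32L, 128L, mode = "sequence"),
    layer_lstm(128L, 64L, mode = "sequence"),
    layer_dropout(0.25),
    layer_lstm(64L, 32L, mode = "last"),
    layer_dropout(0.25),
    layer_dense(32L, spec$output_len)
  )
  types <- vapply(layers, function(l) l$type, character(1L))
  types[length(types)] <- "regression_output"
  model <- new_forecast_model(layers, spec, types)
  init_model(model)
}

#' Build a forecaster from a user-supplied layer stack
#'
#' Accepts a custom description of the hidden layers between the sequence
#' input and the linear regression output. Supported entries:
#' `list(type = "lstm", units =, mode =)`, `list(type = "gru", ...)`,
#' `list(type = "conv", filters =, kernel =, dilation =, elu =)`,
#' `list(type = "batchnorm_elu")`, `list(type = "avgpool", stride =)`,
#' `list(type = "dropout", p =)`. The stack must end in a `"last"`-mode
#' recurrent layer so the regression output sees a feature vector.
#'
#' @param stack List of layer description lists (see above).
#' @param input_len,output_len Context and forecast lengths in samples.
#' @return An untrained `forecast_model` with architecture `"custom"`.
#' @export
build_custom_model <- function(stack, input_len, output_len) {
  spec <- forecast_model_spec("custom", input_len, output_len,
                              hidden_size = 1L)
  layers <- list(layer_identity("sequence_input"))
  width <- 1L
  for (d in stack) {
    l <- switch(d$type,
      lstm = layer_lstm(width, d$units, mode = d$mode %||% "sequence"),
      gru = layer_gru(width, d$units, mode = d$mode %||% "sequence"),
      conv = layer_conv1d(width, d$filters, kernel = d$kernel %||% 5L,
                          dilation = d$dilation %||% 1L,
                          elu = isTRUE(d$elu)),
      batchnorm_elu = layer_batchnorm_elu(width),
      avgpool = layer_avgpool(d$stride %||% 5L),
      dropout = layer_dropout(d$p %||% 0.25),
      stop("unknown custom layer type: ", d$type)
    )
    width <- switch(d$type, lstm = , gru = d$units, conv = d$filters, width)
    layers[[length(layers) + 1L]] <- l
  }
  last <- layers[[length(layers)]]
  ok <- last$type %in% c("lstm", "gru") && last$cfg$mode == "last" ||
    last$type == "dropout"
  if (!ok) stop("custom stack must end in a 'last'-mode recurrent layer (optionally followed by dropout)")
  layers[[length(layers) + 1L]] <- layer_dense(width, output_len)
  types <- vapply(layers, function(l) l$type, character(1L))
  model <- new_forecast_model(layers, spec, types)
  init_model(model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One step of the LSTM cell recurrence
#'
#' Reference implementation of the gated cell update: with sigmoid
#' activations for the forget, update and output gates and tanh for the
#' cell candidate,
#' `f = sigma(W_fh h + W_fx x + b_f)`, `i = sigma(W_ih h + W_ix x + b_i)`,
#' `c_tilde = tanh(W_ch h + W_cx x + b_c)`, `c = f * c_prev + i * c_tilde`,
#' `o = sigma(W_oh h + W_ox x + b_o)`, `h = o * tanh(c)`.
#'
#' @param x_t Input vector (length D).
#' @param h_prev,c_prev Previous hidden and cell state vectors (length H).
#' @param params List with weight matrices `W_fh, W_fx, W_ih, W_ix, W_ch,
#'   W_cx, W_oh, W_ox` (H x H for `*h`, H x D for `*x`) and bias vectors
#'   `b_f, b_i, b_c, b_o`.
#' @return List with the new `h`, `c` and the gate values `f`, `i`,
#'   `c_tilde`, `o` of this step.
#' @export
lstm_cell_step <- function(x_t, h_prev, c_prev, params) {
  H <- length(h_prev)
  D <- length(x_t)
  need <- c("W_fh", "W_fx", "W_ih", "W_ix", "W_ch", "W_cx", "W_oh", "W_ox",
            "b_f", "b_i", "b_c", "b_o")
  if (!all(need %in% names(params))) {
    stop("shape error: params must contain ", paste(need, collapse = ", "))
  }
  for (nm in c("W_fh", "W_ih", "W_ch", "W_oh")) {
    if (!all(dim(params[[nm]]) == c(H, H))) {
      stop("shape error: ", nm, " must be ", H, "x", H)
    }
  }
  for (nm in c("W_fx", "W_ix", "W_cx", "W_ox")) {
    if (!all(dim(params[[nm]]) == c(H, D))) {
      stop("shape error: ", nm, " must be ", H, "x", D)
    }
  }
  if (length(c_prev) != H) stop("shape error: c_prev must have length ", H)
  f <- sigmoid(drop(params$W_fh %*% h_prev + params$W_fx %*% x_t) + params$b_f)
  i <- sigmoid(drop(params$W_ih %*% h_prev + params$W_ix %*% x_t) + params$b_i)
  c_tilde <- tanh(drop(params$W_ch %*% h_prev + params$W_cx %*% x_t) + params$b_c)
  c_t <- f * c_prev + i * c_tilde
  o <- sigmoid(drop(params$W_oh %*% h_prev + params$W_ox %*% x_t) + params$b_o)
  h_t <- o * tanh(c_t)
  list(h = h_t, c = c_t, f = f, i = i, c_tilde = c_tilde, o = o)
}

#' Training configuration
#'
#' Adam with first-moment decay (`beta1`, the reported "momentum") 0.9 and
#' initial learning rate 1e-4. The batch size defaults to 128 (the smaller
#' of the two published settings; 516 was used for the larger corpus). One
#' master `seed` drives weight initialisation, batch shuffling and dropout.
#'
#' @param learning_rate Positive Adam step size.
#' @param beta1,beta2,epsilon Adam moment decays and stabiliser.
#' @param batch_size Examples per optimisation step (>= 1).
#' @param max_epochs Maximum passes over the training examples.
#' @param patience Early-stopping patience in validation checks without
#'   improvement; `Inf` disables early stopping.
#' @param validation_frequency Validation loss is recorded every this many
#'   epochs.
#' @param seed Master integer seed.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, batch_size = 128L, max_epochs = 100L,
                         patience = 10L, validation_frequency = 1L,
                         seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            validation_frequency >= 1, beta1 >= 0, beta1 < 1,
            beta2 >= 0, beta2 < 1)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = patience,
                 validation_frequency = as.integer(validation_frequency),
                 seed = as.integer(seed)),
            class = "train_config")
}

## Cut segments into non-overlapping (context, target) example pairs.
training_examples <- function(segments, input_len, output_len) {
  ex_len <- input_len + output_len
  xs <- list(); ys <- list()
  for (seg in segments) {
    n_ex <- length(seg) %/% ex_len
    for (e in seq_len(n_ex)) {
      i0 <- (e - 1L) * ex_len
      xs[[length(xs) + 1L]] <- seg[i0 + seq_len(input_len)]
      ys[[length(ys) + 1L]] <- seg[i0 + input_len + seq_len(output_len)]
    }
  }
  if (length(xs) == 0L) {
    stop("insufficient data: no segment is at least input_len + output_len samples long")
  }
  list(X = matrix(unlist(xs), nrow = input_len),
       Y = matrix(unlist(ys), nrow = output_len))
}

resolve_split <- function(data, which) {
  if (inherits(data, "segment_set")) {
    if (is.null(data$split)) stop("segment set has not been split yet")
    segments_split(data, which)
  } else if (is.list(data)) {
    data
  } else if (is.numeric(data)) {
    list(data)
  } else {
    stop("expected a segment_set or a list of sample vectors")
  }
}

eq3_loss <- function(pred, truth) {
  sum((pred - truth)^2) / (2 * nrow(truth))
}

#' Train a forecaster on artefact-free segments
#'
#' Minimises the half-mean-squared forecast error (see [half_mse_loss()])
#' with Adam. Inputs and targets are z-scored with the training-set mean
#' and standard deviation, which are stored in the model and applied
#' transparently by [forecast()]. Weights are (re-)initialised from the
#' master seed at the start of training so a run is fully reproducible from
#' its configuration. For the optimiser update the gradient of the
#' per-example mean loss is used, so the learning rate is batch-size
#' independent; the recorded history is the printed loss over the full set.
#'
#' @param model An untrained model from [build_lstm()], [build_cnn_lstm()]
#'   or [build_custom_model()]. Modified in place and returned.
#' @param train,val Lists of artefact-free sample vectors, or a
#'   [split_segments()] `segment_set` (in which case `train` supplies both
#'   and `val` may be omitted). Each segment must be at least
#'   `input_len + output_len` samples long to contribute examples.
#' @param cfg A [train_config()].
#' @return List with `model` (trained) and `history`, a data frame of
#'   `epoch`, `train_loss` and `val_loss` at each validation interval.
#' @export
train_forecaster <- function(model, train, val = NULL, cfg = train_config()) {
  stopifnot(inherits(model, "forecast_model"), inherits(cfg, "train_config"))
  if (inherits(train, "segment_set") && is.null(val)) {
    val <- resolve_split(train, "val")
    train <- resolve_split(train, "train")
  } else {
    train <- resolve_split(train, "train")
    if (!is.null(val)) val <- resolve_split(val, "val")
  }
  I <- model$spec$input_len
  O <- model$spec$output_len
  tr <- training_examples(train, I, O)
  mu <- mean(c(tr$X, tr$Y))
  sdv <- stats::sd(c(tr$X, tr$Y))
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  model$norm <- list(mean = mu, sd = sdv)
  Xtr <- (tr$X - mu) / sdv
  Ytr <- (tr$Y - mu) / sdv
  has_val <- !is.null(val) && length(val) > 0L
  if (has_val) {
    va <- training_examples(val, I, O)
    Xva <- (va$X - mu) / sdv
    Yva <- (va$Y - mu) / sdv
  }
  N <- ncol(Xtr)
  hist_epoch <- integer(0); hist_train <- numeric(0); hist_val <- numeric(0)
  best_val <- Inf; best_snap <- NULL; wait <- 0L
  withr::with_seed(cfg$seed, {
    for (l in model$layers) init_layer_params(l)
    step <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample.int(N)
      epoch_loss <- 0
      for (b0 in seq(1L, N, by = cfg$batch_size)) {
        idx <- perm[b0:min(b0 + cfg$batch_size - 1L, N)]
        Xb <- Xtr[, idx, drop = FALSE]
        Yb <- Ytr[, idx, drop = FALSE]
        pred <- model_forward(model, Xb, training = TRUE)
        diff <- pred - Yb
        batch_loss <- sum(diff^2) / (2 * O)
        if (!is.finite(batch_loss)) {
          stop(sprintf("divergence error: non-finite loss at epoch %d", epoch))
        }
        epoch_loss <- epoch_loss + batch_loss
        zero_grads(model)
        dy <- diff / (O * length(idx))
        for (layer in rev(model$layers)) dy <- layer_backward(layer, dy)
        step <- step + 1L
        adam_step(model, cfg$learning_rate, cfg$beta1, cfg$beta2,
                  cfg$epsilon, step)
      }
      if (epoch %% cfg$validation_frequency == 0L) {
        vloss <- NA_real_
        if (has_val) {
          vpred <- model_forward(model, Xva, training = FALSE)
          vloss <- eq3_loss(vpred, Yva)
          if (!is.finite(vloss)) {
            stop(sprintf("divergence error: non-finite validation loss at epoch %d", epoch))
          }
        }
        hist_epoch <- c(hist_epoch, epoch)
        hist_train <- c(hist_train, epoch_loss)
        hist_val <- c(hist_val, vloss)
        if (has_val) {
          if (vloss < best_val - 1e-12) {
            best_val <- vloss
            best_snap <- snapshot_params(model)
            wait <- 0L
          } else {
            wait <- wait + 1L
            if (is.finite(cfg$patience) && wait >= cfg$patience) break
          }
        }
      }
    }
  })
  if (!is.null(best_snap)) restore_params(model, best_snap)
  model$trained <- TRUE
  list(model = model,
       history = data.frame(epoch = hist_epoch, train_loss = hist_train,
                            val_loss = hist_val))
}

#' Forecast future samples from a context
#'
#' Dispatches on the model class: trained sequence networks z-score the
#' context with their stored training statistics, run the forward pass and
#' de-normalise back to millivolts; ARMAX specs forecast by linear
#' recursion (see [fit_armax()]); stub models call their prediction
#' function.
#'
#' @param model A `forecast_model`, `armax_spec` or `forecast_stub`.
#' @param context Numeric vector of past samples (mV). Networks require
#'   exactly `input_len` samples.
#' @param ... Further arguments for methods (`horizon` for ARMAX).
#' @return Numeric vector of predicted samples in mV.
#' @export
forecast <- function(model, context, ...) UseMethod("forecast")

#' @export
forecast.forecast_model <- function(model, context, ...) {
  I <- model$spec$input_len
  if (length(context) != I) {
    stop(sprintf("shape error: context must have %d samples, got %d",
                 I, length(context)))
  }
  xn <- (context - model$norm$mean) / model$norm$sd
  pred <- model_forward(model, matrix(xn, ncol = 1L), training = FALSE)
  drop(pred) * model$norm$sd + model$norm$mean
}

#' Stub forecasters for baselines and testing
#'
#' `zoh_model()` is the zero-order-hold baseline that repeats the last
#' context sample over the whole output; `constant_model()` always predicts
#' a fixed value; `stub_model()` wraps an arbitrary prediction function
#' `fun(context) -> numeric(output_len)`.
#'
#' @param input_len,output_len Context and forecast lengths in samples.
#' @param value Constant prediction for `constant_model()`.
#' @param fun Prediction function for `stub_model()`.
#' @return An object of class `forecast_stub` usable with [forecast()] and
#'   [recursive_forecast()].
#' @export
stub_model <- function(fun, input_len, output_len) {
  structure(list(fun = fun,
                 spec = list(architecture = "stub",
                             input_len = as.integer(input_len),
                             output_len = as.integer(output_len))),
            class = "forecast_stub")
}

#' @rdname stub_model
#' @export
zoh_model <- function(input_len, output_len) {
  m <- stub_model(function(context) rep(context[length(context)], output_len),
                  input_len, output_len)
  m$spec$architecture <- "zero_order_hold"
  m
}

#' @rdname stub_model
#' @export
constant_model <- function(value, input_len, output_len) {
  stub_model(function(context) rep(value, output_len), input_len, output_len)
}

#' @export
forecast.forecast_stub <- function(model, context, ...) {
  if (length(context) != model$spec$input_len) {
    stop(sprintf("shape error: context must have %d samples, got %d",
                 model$spec$input_len, length(context)))
  }
  out <- model$fun(context)
  if (length(out) != model$spec$output_len) {
    stop("shape error: stub returned wrong output length")
  }
  out
}
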
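#' Per-channel power threshold specification
#'
#' @param values Numeric vector of non-negative, finite threshold values
#'   (mV^2), either one global value or one per channel.
#' @param provenance How the threshold was obtained: typed in by the user
#'   (`"manual"`) or computed from labelled artefact-free epochs
#'   (`"derived_from_clean_epochs"`).
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(values,
                           provenance = c("manual", "derived_from_clean_epochs")) {
  provenance <- match.arg(provenance)
  if (!is.numeric(values) || length(values) < 1L ||
      !all(is.finite(values)) || any(values < 0)) {
    stop("threshold values must be non-negative and finite")
  }
  structure(list(values = as.numeric(values), provenance = provenance),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("<threshold_spec> %s: %s mV^2\n", x$provenance,
              paste(signif(x$values, 6), collapse = ", ")))
  invisible(x)
}

#' Derive a power threshold from artefact-free epochs
#'
#' The threshold is the maximum mean-square power over all complete windows
#' of the supplied artefact-free epochs: any window of new data whose power
#' strictly exceeds it is labelled artefactual.
#'
#' @param clean_epochs List of numeric sample vectors, each at least one
#'   window long; typically epochs identified as artefact-free by visual
#'   inspection or a withheld clean reference.
#' @param grid A [make_windows()] grid supplying the window length.
#' @return A [threshold_spec()] with provenance
#'   `"derived_from_clean_epochs"`.
#' @export
derive_threshold <- function(clean_epochs, grid) {
  stopifnot(inherits(grid, "window_grid"))
  if (is.numeric(clean_epochs)) clean_epochs <- list(clean_epochs)
  if (!is.list(clean_epochs) || length(clean_epochs) == 0L) {
    stop("`clean_epochs` must be a non-empty list of sample vectors")
  }
  L <- grid$window_len
  pmax_all <- -Inf
  for (k in seq_along(clean_epochs)) {
    ep <- clean_epochs[[k]]
    if (length(ep) < L) {
      stop(sprintf("invalid epoch %d: shorter than one window (%d < %d samples)",
                   k, length(ep), L))
    }
    nw <- length(ep) %/% L
    x <- ep[seq_len(nw * L)]
    dim(x) <- c(L, nw)
    pmax_all <- max(pmax_all, colMeans(x^2))
  }
  threshold_spec(pmax_all, provenance = "derived_from_clean_epochs")
}

#' Label windows as artefactual by power threshold
#'
#' A window is labelled 1 (artefact) iff its mean-square power strictly
#' exceeds the channel's threshold; a window exactly at the threshold is
#' labelled clean.
#'
#' @param recording An [recording()] object.
#' @param grid A [make_windows()] grid on that recording.
#' @param thr A [threshold_spec()] with either one global value or one
#'   value per channel.
#' @return An object of class `label_array`: a binary channels x windows
#'   matrix `labels` plus the `grid` it indexes.
#' @export
label_windows <- function(recording, grid, thr) {
  stopifnot(inherits(thr, "threshold_spec"))
  nch <- n_channels(recording)
  vals <- thr$values
  if (length(vals) == 1L) vals <- rep(vals, nch)
  if (length(vals) != nch) {
    stop("dimension error: threshold must have one value per channel")
  }
  pw <- window_powers(recording, grid)
  labels <- (pw > vals) + 0L
  storage.mode(labels) <- "integer"
  dimnames(labels) <- NULL
  structure(list(labels = labels, grid = grid), class = "label_array")
}

#' @export
print.label_array <- function(x, ...) {
  cat(sprintf("<label_array> %d channel(s) x %d windows, %d artefactual\n",
              nrow(x$labels), ncol(x$labels), sum(x$labels)))
  invisible(x)
}

segment_windows <- function(segment_seconds, grid, what = "segment") {
  n <- segment_seconds * grid$fs / grid$window_len
  if (abs(n - round(n)) > 1e-8 || n < 1) {
    stop(sprintf("geometry error: %s length must be an integer multiple of the window length",
                 what))
  }
  as.integer(round(n))
}

## Single greedy left-to-right scan over the window labels of one channel.
## At each position it first tries to emit a fully clean segment (if
## enabled), then an artefactual segment with a clean prefix (if enabled),
## otherwise advances one window. Running it with both kinds enabled
## guarantees the two segment families never overlap in sample coverage.
scan_segments <- function(lab, seg_w, prefix_w, emit_clean, emit_artefactual) {
  nwin <- length(lab)
  clean_starts <- integer(0)
  art_starts <- integer(0)
  s <- 1L
  while (s + seg_w - 1L <= nwin) {
    block <- lab[s:(s + seg_w - 1L)]
    if (emit_clean && all(block == 0L)) {
      clean_starts <- c(clean_starts, s)
      s <- s + seg_w
    } else if (emit_artefactual && !is.null(prefix_w) &&
               all(block[seq_len(prefix_w)] == 0L) && any(block == 1L)) {
      art_starts <- c(art_starts, s)
      s <- s + seg_w
    } else {
      s <- s + 1L
    }
  }
  list(clean = clean_starts, artefactual = art_starts)
}

new_segment_set <- function(clean, clean_meta, artefactual, art_meta,
                            segment_len, clean_prefix_len, grid) {
  structure(list(
    clean = clean,
    clean_meta = clean_meta,
    artefactual = artefactual,
    artefactual_meta = art_meta,
    segment_len = segment_len,
    clean_prefix_len = clean_prefix_len,
    grid = grid,
    split = NULL,
    seed = NULL
  ), class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d clean + %d artefactual segments of %d samples",
              length(x$clean), length(x$artefactual), x$segment_len))
  if (!is.null(x$clean_prefix_len)) {
    cat(sprintf(" (clean prefix %d samples)", x$clean_prefix_len))
  }
  cat("\n")
  if (!is.null(x$split)) {
    cat(sprintf("  split: %s (seed %s)\n",
                paste(names(table(x$split)), table(x$split),
                      sep = "=", collapse = " "), x$seed))
  }
  invisible(x)
}

extract_segments_impl <- function(recording, labels, segment_seconds,
                                  clean_prefix_seconds = NULL,
                                  emit_clean = TRUE, emit_artefactual = TRUE) {
  stopifnot(inherits(recording, "lfp_recording"), inherits(labels, "label_array"))
  grid <- labels$grid
  check_grid_match(recording, grid)
  if (nrow(labels$labels) != n_channels(recording)) {
    stop("dimension error: labels and recording channel counts differ")
  }
  seg_w <- segment_windows(segment_seconds, grid, "segment")
  prefix_w <- NULL
  if (!is.null(clean_prefix_seconds)) {
    prefix_w <- segment_windows(clean_prefix_seconds, grid, "clean prefix")
    if (prefix_w >= seg_w) {
      stop("geometry error: clean prefix must be shorter than the segment")
    }
  }
  L <- grid$window_len
  seg_len <- seg_w * L
  clean <- list(); art <- list(); art_lab <- list()
  cm <- list(channel = integer(0), start_window = integer(0),
             start_sample = integer(0))
  am <- cm
  for (ch in seq_len(n_channels(recording))) {
    lab <- labels$labels[ch, ]
    hits <- scan_segments(lab, seg_w, prefix_w, emit_clean, emit_artefactual)
    for (s in hits$clean) {
      i0 <- (s - 1L) * L + 1L
      clean[[length(clean) + 1L]] <- recording$data[ch, i0:(i0 + seg_len - 1L)]
      cm$channel <- c(cm$channel, ch)
      cm$start_window <- c(cm$start_window, s)
      cm$start_sample <- c(cm$start_sample, i0)
    }
    for (s in hits$artefactual) {
      i0 <- (s - 1L) * L + 1L
      art[[length(art) + 1L]] <- recording$data[ch, i0:(i0 + seg_len - 1L)]
      art_lab[[length(art_lab) + 1L]] <- lab[s:(s + seg_w - 1L)]
      am$channel <- c(am$channel, ch)
      am$start_window <- c(am$start_window, s)
      am$start_sample <- c(am$start_sample, i0)
    }
  }
  new_segment_set(
    clean, as.data.frame(cm),
    mapply(function(x, l) list(samples = x, window_labels = l),
           art, art_lab, SIMPLIFY = FALSE),
    as.data.frame(am),
    seg_len,
    if (is.null(prefix_w)) NULL else prefix_w * L,
    grid
  )
}

#' Extract artefact-free segments
#'
#' Scans each channel's window labels left to right and greedily extracts
#' non-overlapping fixed-length segments whose constituent windows are all
#' labelled clean.
#'
#' @param recording An [recording()] object.
#' @param labels A [label_windows()] result on the recording's grid.
#' @param segment_seconds Segment duration; must be an integer multiple of
#'   the label window length.
#' @return A `segment_set` whose `clean` element is the list of extracted
#'   sample vectors (see also `clean_meta` for channel/offset bookkeeping).
#' @export
extract_clean_segments <- function(recording, labels, segment_seconds) {
  extract_segments_impl(recording, labels, segment_seconds,
                        emit_clean = TRUE, emit_artefactual = FALSE)
}

#' Extract artefactual segments with a clean prefix
#'
#' Extracts non-overlapping fixed-length segments that contain at least one
#' artefact-labelled window but whose first `clean_prefix_seconds` are
#' entirely artefact-free, so the prefix can serve as forecasting context.
#'
#' @inheritParams extract_clean_segments
#' @param clean_prefix_seconds Required artefact-free prefix duration;
#'   shorter than `segment_seconds` and a multiple of the window length.
#' @return A `segment_set` whose `artefactual` element is a list of
#'   `list(samples, window_labels)` pairs.
#' @export
extract_artefactual_segments <- function(recording, labels, segment_seconds,
                                         clean_prefix_seconds) {
  extract_segments_impl(recording, labels, segment_seconds,
                        clean_prefix_seconds,
                        emit_clean = FALSE, emit_artefactual = TRUE)
}

#' Extract clean and artefactual segments in one disjoint scan
#'
#' Runs the same greedy scan with both segment kinds enabled, so the clean
#' and artefactual segment families are guaranteed not to overlap in sample
#' coverage. Used by the end-to-end pipeline.
#'
#' @inheritParams extract_artefactual_segments
#' @return A `segment_set` with both `clean` and `artefactual` populated.
#' @export
extract_segments <- function(recording, labels, segment_seconds,
                             clean_prefix_seconds) {
  extract_segments_impl(recording, labels, segment_seconds,
                        clean_prefix_seconds,
                        emit_clean = TRUE, emit_artefactual = TRUE)
}

#' Randomly split clean segments into train / validation / test sets
#'
#' Segment-level i.i.d. random assignment with a fixed seed. Validation and
#' test receive `round(fraction * n)` segments each and the remainder goes
#' to the training set.
#'
#' @param segs A `segment_set`.
#' @param fractions Positive train/val/test fractions summing to 1.
#' @param seed Integer seed making the assignment repeatable.
#' @return The `segment_set` with a `split` factor (levels train/val/test)
#'   over its clean segments and the `seed` recorded.
#' @export
split_segments <- function(segs, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(inherits(segs, "segment_set"))
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("`fractions` must be three positive values summing to 1")
  }
  n <- length(segs$clean)
  if (n < 3L) stop("insufficient data: need at least 3 clean segments to split")
  n_val <- round(fractions[2] * n)
  n_test <- round(fractions[3] * n)
  n_train <- n - n_val - n_test
  if (n_train < 1L) stop("insufficient data: no segments left for training")
  perm <- withr::with_seed(seed, sample.int(n))
  split <- factor(rep(NA_character_, n), levels = c("train", "val", "test"))
  split[perm[seq_len(n_train)]] <- "train"
  if (n_val > 0) split[perm[n_train + seq_len(n_val)]] <- "val"
  if (n_test > 0) split[perm[n_train + n_val + seq_len(n_test)]] <- "test"
  segs$split <- split
  segs$seed <- as.integer(seed)
  segs
}

#' Clean segments belonging to one split
#'
#' @param segs A [split_segments()] result.
#' @param which One of `"train"`, `"val"`, `"test"`.
#' @return List of numeric sample vectors.
#' @export
segments_split <- function(segs, which = c("train", "val", "test")) {
  which <- match.arg(which)
  stopifnot(inherits(segs, "segment_set"))
  if (is.null(segs$split)) stop("segments have not been split yet")
  segs$clean[segs$split == which]
}

#' Cartesian grid of forecaster input/output configurations
#'
#' @param input_seconds Strictly positive, duplicate-free input context
#'   lengths in seconds.
#' @param output_lengths Strictly positive, duplicate-free forecast output
#'   lengths in samples.
#' @return Data frame with columns `input_s` and `output_len`, ordered
#'   input-major (all outputs for the first input, then the second, ...).
#' @export
#' @examples
#' nrow(build_config_grid(seq(0.1, 0.9, by = 0.1), c(1, 5, 10, 25, 50, 100)))
build_config_grid <- function(input_seconds, output_lengths) {
  if (length(input_seconds) == 0L || length(output_lengths) == 0L) {
    stop("invalid grid: both lists must be non-empty")
  }
  if (any(input_seconds <= 0) || any(output_lengths <= 0)) {
    stop("invalid grid: entries must be strictly positive")
  }
  if (anyDuplicated(input_seconds) || anyDuplicated(output_lengths)) {
    stop("invalid grid: duplicate entries")
  }
  data.frame(
    input_s = rep(input_seconds, each = length(output_lengths)),
    output_len = as.integer(rep(output_lengths, times = length(input_seconds)))
  )
}
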
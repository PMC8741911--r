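#' Read a recording from disk
#'
#' Supported formats: delimited ASCII text (channels as rows; delimiter
#' auto-detected among comma, tab and space), the package's simple binary
#' matrix container (see [write_recording()]), and MATLAB Level 4 (v4)
#' `.mat` files containing one numeric matrix (v5/v7 files are not
#' supported and raise a clear error). None of these formats carries a
#' sampling rate, so `fs` must always be supplied.
#'
#' @param path File path.
#' @param format One of `"delimited"`, `"binary_matrix"`, `"mat"`.
#' @param fs Sampling frequency in Hz.
#' @param scale Amplitude factor applied on load (e.g. 1000 for a file
#'   recorded in volts to obtain mV).
#' @param channel_ids Optional channel labels.
#' @return An [recording()] object.
#' @export
read_recording <- function(path, format = c("delimited", "binary_matrix", "mat"),
                           fs, scale = 1, channel_ids = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(fs)) stop("prerequisite error: `fs` must be supplied (formats carry no rate metadata)")
  data <- switch(format,
    delimited = read_delimited_matrix(path),
    binary_matrix = read_binary_matrix(path),
    mat = read_mat4_matrix(path)
  )
  recording(data, fs = fs, scale = scale, channel_ids = channel_ids)
}

detect_delim <- function(line) {
  if (grepl(",", line, fixed = TRUE)) return(",")
  if (grepl("\t", line, fixed = TRUE)) return("\t")
  " "
}

read_delimited_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("parse error: empty file")
  delim <- detect_delim(lines[[1L]])
  split_re <- if (delim == " ") "[ \t]+" else delim
  rows <- lapply(lines, function(l) strsplit(trimws(l), split_re)[[1L]])
  n_col <- length(rows[[1L]])
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != n_col) {
      stop(sprintf("parse error: row %d has %d fields, expected %d",
                   i, length(rows[[i]]), n_col))
    }
  }
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop(sprintf("parse error: non-numeric cell at row %d, column %d",
                 (bad - 1L) %/% n_col + 1L, (bad - 1L) %% n_col + 1L))
  }
  matrix(vals, nrow = length(rows), byrow = TRUE)
}

BINARY_MAGIC <- "LFPM"
BINARY_VERSION <- 1L

read_binary_matrix <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(magic, BINARY_MAGIC)) {
    stop("parse error: not a binary matrix file (bad magic)")
  }
  ver <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (ver != BINARY_VERSION) {
    stop("version error: unsupported binary matrix version ", ver)
  }
  nch <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  ns <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  vals <- readBin(con, "double", nch * ns, size = 8L, endian = "little")
  if (length(vals) != nch * ns) stop("parse error: truncated binary matrix")
  matrix(vals, nrow = nch, byrow = FALSE)
}

#' Write a recording to disk
#'
#' Writes the stored (already scaled) sample matrix; reading it back with
#' `scale = 1` reproduces the amplitudes. The binary container is
#' `"LFPM"`, a version integer, channel and sample counts (little-endian
#' int32) followed by column-major little-endian doubles, and round-trips
#' bitwise.
#'
#' @param recording An [recording()] object.
#' @param path Output path.
#' @param format `"delimited"` (comma-separated, channels as rows),
#'   `"binary_matrix"`, or `"mat"` (MATLAB Level 4).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path,
                            format = c("delimited", "binary_matrix", "mat")) {
  format <- match.arg(format)
  stopifnot(inherits(recording, "lfp_recording"))
  switch(format,
    delimited = utils::write.table(
      recording$data, path, sep = ",", row.names = FALSE, col.names = FALSE),
    binary_matrix = {
      con <- file(path, "wb")
      on.exit(close(con))
      writeBin(charToRaw(BINARY_MAGIC), con)
      writeBin(c(BINARY_VERSION, n_channels(recording), n_samples(recording)),
               con, size = 4L, endian = "little")
      writeBin(as.vector(recording$data), con, size = 8L, endian = "little")
    },
    mat = write_mat4_matrix(recording$data, path)
  )
  invisible(path)
}

## MATLAB Level 4 (v4) MAT files: 20-byte header of int32s
## (type, mrows, ncols, imagf, namlen), the NUL-terminated variable name,
## then column-major data. Only little-endian double real matrices
## (type 0) are handled; v5/v7 files start with a text header and are
## rejected with a pointer to convert.
read_mat4_matrix <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", 5L, size = 4L, endian = "little")
  if (length(hdr) < 5L) stop("parse error: truncated .mat file")
  type <- hdr[1L]
  if (type < 0 || type > 4052) {
    stop("version error: not a Level 4 .mat file; v5/v7 files are not supported, convert with `save -v4` or export delimited text")
  }
  ## type digits are MOPT: machine, O (always 0), precision, matrix type
  if (type %/% 1000 != 0 || (type %/% 10) %% 10 != 0 || type %% 10 != 0) {
    stop("parse error: only little-endian double-precision numeric v4 matrices are supported")
  }
  mrows <- hdr[2L]; ncols <- hdr[3L]; imagf <- hdr[4L]; namlen <- hdr[5L]
  if (imagf != 0) stop("parse error: complex matrices are not supported")
  readBin(con, "raw", namlen) # variable name, unused
  vals <- readBin(con, "double", mrows * ncols, size = 8L, endian = "little")
  if (length(vals) != mrows * ncols) stop("parse error: truncated .mat data")
  matrix(vals, nrow = mrows)
}

write_mat4_matrix <- function(m, path, name = "lfp") {
  con <- file(path, "wb")
  on.exit(close(con))
  nm <- c(charToRaw(name), as.raw(0L))
  writeBin(as.integer(c(0L, nrow(m), ncol(m), 0L, length(nm))),
           con, size = 4L, endian = "little")
  writeBin(nm, con)
  writeBin(as.vector(m), con, size = 8L, endian = "little")
  invisible(path)
}

BUNDLE_SCHEMA <- "1.0"

#' Result bundle
#'
#' The self-describing saved artifact of a pipeline run: source filename,
#' threshold spec, window length, scale, labels, trained model (weights
#' included), training history, test-set RMSE, original and replaced test
#' segments, cleaned recording, replacement log, tool version, master
#' seed and config hash. Every field except `source_file` and `seed` is
#' optional so stages can fill the bundle incrementally; a bundle without
#' model weights loads with the model marked untrained.
#'
#' @param source_file Original input filename.
#' @param seed Master seed of the run.
#' @param ... Further fields (see above), e.g. `labels =`, `threshold =`,
#'   `model =`, `history =`, `test_rmse =`, `cleaned_recording =`,
#'   `replacement_log =`, `config =`, `config_hash =`, `fs =`,
#'   `window_seconds =`, `scale =`.
#' @return An object of class `lfp_bundle`.
#' @export
result_bundle <- function(source_file, seed, ...) {
  structure(c(list(schema_version = BUNDLE_SCHEMA,
                   tool_version = as.character(utils::packageVersion("lfpclean")),
                   source_file = source_file,
                   seed = as.integer(seed)),
              list(...)),
            class = "lfp_bundle")
}

#' Save / load a result bundle
#'
#' Bundles are stored as a single uncompressed RDS container, which
#' round-trips all numeric payloads losslessly and byte-identically:
#' save -> load -> save produces the same file.
#'
#' @param bundle An [result_bundle()].
#' @param path File path (conventionally `.lfpb`).
#' @return `save_bundle()` returns `path` invisibly; `load_bundle()`
#'   returns the bundle.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "lfp_bundle"))
  tmp <- paste0(path, ".tmp")
  saveRDS(bundle, tmp, compress = FALSE)
  file.rename(tmp, path) # never leave a partial bundle behind
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  b <- readRDS(path)
  if (!inherits(b, "lfp_bundle") || is.null(b$schema_version)) {
    stop("version error: not an lfpclean bundle")
  }
  if (!identical(b$schema_version, BUNDLE_SCHEMA)) {
    stop(sprintf("version error: bundle schema %s, this build reads %s",
                 b$schema_version, BUNDLE_SCHEMA))
  }
  if (!is.null(b$model) && inherits(b$model, "forecast_model") &&
      is.null(b$model$trained)) {
    b$model$trained <- FALSE
  }
  b
}

#' @export
print.lfp_bundle <- function(x, ...) {
  filled <- setdiff(names(x)[!vapply(x, is.null, logical(1L))],
                    c("schema_version", "tool_version"))
  cat(sprintf("<lfp_bundle> schema %s (tool %s), seed %d\n  fields: %s\n",
              x$schema_version, x$tool_version, x$seed,
              paste(filled, collapse = ", ")))
  invisible(x)
}

PIPELINE_KEYS <- c(
  "fs", "scale", "window_seconds", "threshold_mode", "threshold_value",
  "segment_seconds", "clean_prefix_seconds", "fractions", "architecture",
  "input_seconds", "output_len", "hidden_size", "learning_rate",
  "batch_size", "max_epochs", "patience", "validation_frequency",
  "horizon_samples", "seed", "duration_s", "sigma", "event_rate_per_min",
  "event_amplitude", "n_channels"
)

#' Default pipeline configuration
#'
#' One plain-text key-value (YAML) document holds every tunable of the
#' pipeline. Defaults mirror the sleep-study scale: 250 Hz, 1-s windows,
#' 4-s segments with a 1-s clean prefix, an LSTM with a 1-s input and 1-s
#' output, 80/10/10 splits and a 250-sample evaluation horizon.
#'
#' @return Named list of configuration values.
#' @export
default_pipeline_config <- function() {
  list(
    fs = 250, scale = 1, window_seconds = 1,
    threshold_mode = "derived", threshold_value = NA,
    segment_seconds = 4, clean_prefix_seconds = 1,
    fractions = c(0.8, 0.1, 0.1),
    architecture = "lstm", input_seconds = 1, output_len = 250,
    hidden_size = NA,
    learning_rate = 1e-4, batch_size = 128, max_epochs = 50,
    patience = 10, validation_frequency = 1,
    horizon_samples = 250, seed = 1,
    duration_s = 600, sigma = 0.05,
    event_rate_per_min = 3, event_amplitude = 10, n_channels = 1
  )
}

#' Read and validate a pipeline configuration file
#'
#' Unknown keys are rejected; missing keys fall back to
#' [default_pipeline_config()]. The MD5 hash of the file is recorded so
#' bundles are traceable to the exact configuration.
#'
#' @param path YAML key-value file.
#' @return The merged configuration list with attribute `"hash"`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), PIPELINE_KEYS)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  out <- utils::modifyList(default_pipeline_config(), cfg)
  attr(out, "hash") <- unname(tools::md5sum(path))
  out
}

config_hash <- function(cfg) {
  h <- attr(cfg, "hash")
  if (!is.null(h)) return(h)
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg[order(names(cfg))], tmp)
  unname(tools::md5sum(tmp))
}

#' Per-rodent awake-segment durations of the treadmill data set
#'
#' The published per-recording durations (seconds) of visually inspected
#' awake treadmill segments, with the per-rodent totals as printed.
#' Useful for consistency checks: each rodent's total equals the sum of
#' its recordings.
#'
#' @return Data frame with columns `rodent`, `recording_id`, `seconds`,
#'   `rodent_total_s`.
#' @export
treadmill_awake_table <- function() {
  path <- system.file("extdata", "treadmill_awake_segments.csv",
                      package = "lfpclean", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
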
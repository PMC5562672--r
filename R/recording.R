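#' Multi-channel raw recording container
#'
#' A `raw_recording` holds a voltage trace in microvolts, one row per channel,
#' together with its sampling rate. Single-electrode data has one channel,
#' tetrode data four; any channel count is accepted.
#'
#' @param samples Numeric matrix (`n_channels x n_samples`) of voltages in
#'   microvolts, or a plain numeric vector for single-channel data.
#' @param sampling_rate_hz Positive sampling rate in Hz (30000 for the
#'   datasets this workflow targets).
#' @return An object of class `raw_recording` with fields `samples` (matrix)
#'   and `sampling_rate_hz`.
#' @export
raw_recording <- function(samples, sampling_rate_hz) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be a single positive number")
  }
  structure(
    list(samples = samples, sampling_rate_hz = as.numeric(sampling_rate_hz)),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf(
    "<raw_recording> %d channel(s), %d samples @ %g Hz (%.2f s)\n",
    nrow(x$samples), ncol(x$samples), x$sampling_rate_hz,
    ncol(x$samples) / x$sampling_rate_hz
  ))
  invisible(x)
}

#' Number of channels / samples of a recording
#' @param rec A [raw_recording()].
#' @return Integer count.
#' @export
n_channels <- function(rec) nrow(rec$samples)

#' @rdname n_channels
#' @export
n_samples <- function(rec) ncol(rec$samples)

#' Read a flat binary recording
#'
#' Reads a channel-interleaved little-endian signed-integer file (the common
#' raw format written by acquisition systems) and scales it to microvolts.
#'
#' @param path File to read.
#' @param n_channels Number of interleaved channels in the file.
#' @param sampling_rate_hz Sampling rate of the stored trace.
#' @param scale_uV Microvolts per integer unit (default 1).
#' @param bytes Bytes per stored sample, 2 for int16 (default) or 4 for int32.
#' @return A [raw_recording()].
#' @export
read_raw_binary <- function(path, n_channels, sampling_rate_hz,
                            scale_uV = 1, bytes = 2L) {
  stopifnot(file.exists(path), n_channels >= 1)
  sz <- file.info(path)$size
  if (sz %% (n_channels * bytes) != 0) {
    stop(sprintf(
      "truncated or mislabelled file: %d bytes is not a multiple of %d channels x %d bytes",
      sz, n_channels, bytes
    ))
  }
  n_total <- sz / bytes
  v <- readBin(path, what = "integer", n = n_total, size = bytes,
               signed = TRUE, endian = "little")
  m <- matrix(as.numeric(v) * scale_uV, nrow = n_channels)
  raw_recording(m, sampling_rate_hz)
}

#' Write a flat binary recording
#'
#' Inverse of [read_raw_binary()]: voltages are divided by `scale_uV`, rounded
#' to the nearest integer and stored channel-interleaved, little-endian.
#'
#' @inheritParams read_raw_binary
#' @param rec A [raw_recording()].
#' @return `path`, invisibly.
#' @export
write_raw_binary <- function(rec, path, scale_uV = 1, bytes = 2L) {
  v <- as.integer(round(as.vector(rec$samples) / scale_uV))
  writeBin(v, path, size = bytes, endian = "little")
  invisible(path)
}

#' Save / load workflow objects
#'
#' Internal persistence for recordings, spike sets, template lists and banks
#' uses R's native serialization; these are thin wrappers kept so every stage
#' of the command-line workflow reads and writes through one documented pair.
#'
#' @param x Any workflow object.
#' @param path Destination file.
#' @return `save_object` returns `path` invisibly; `load_object` the object.
#' @export
save_object <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname save_object
#' @export
load_object <- function(path) readRDS(path)
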
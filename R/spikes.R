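#' Trough-aligned spike waveform set
#'
#' A `spike_set` stores extracted spikes as an `n_spikes x n_channels x 32`
#' array of microvolt snippets together with the absolute trigger time of each
#' spike. Every waveform is aligned so that its trough (the local minimum that
#' triggered extraction) sits at local sample 11 of 32 (1-based; 10 samples
#' precede the trigger and 21 follow it, i.e. about 1 ms at 30 kHz).
#'
#' @param waveforms Numeric array `n_spikes x n_channels x n_window` (the
#'   window is 32 samples throughout this workflow). A matrix is accepted for
#'   single-channel data (`n_spikes x 32`).
#' @param trigger_times Integer vector of absolute 1-based sample indices of
#'   each trigger in the source recording; must be strictly increasing.
#' @param trigger_channels Optional integer vector giving, per spike, the
#'   channel whose trough triggered extraction (default 1).
#' @param source_id Free-text provenance tag.
#' @return An object of class `spike_set`.
#' @export
spike_set <- function(waveforms, trigger_times,
                      trigger_channels = NULL, source_id = "") {
  if (length(dim(waveforms)) == 2L) {
    waveforms <- array(waveforms, dim = c(nrow(waveforms), 1L, ncol(waveforms)))
  }
  stopifnot(length(dim(waveforms)) == 3L)
  n <- dim(waveforms)[1L]
  if (length(trigger_times) != n) {
    stop("trigger_times length must equal the number of waveforms")
  }
  if (n > 1L && any(diff(trigger_times) <= 0)) {
    stop("trigger_times must be strictly increasing")
  }
  if (is.null(trigger_channels)) trigger_channels <- rep(1L, n)
  structure(
    list(
      waveforms = waveforms,
      trigger_times = as.integer(trigger_times),
      trigger_channels = as.integer(trigger_channels),
      source_id = source_id
    ),
    class = "spike_set"
  )
}

#' @export
print.spike_set <- function(x, ...) {
  d <- dim(x$waveforms)
  cat(sprintf("<spike_set> %d spikes, %d channel(s), %d-sample window\n",
              d[1L], d[2L], d[3L]))
  invisible(x)
}

#' Number of spikes in a spike set
#' @param spikes A [spike_set()].
#' @return Integer count.
#' @export
n_spikes <- function(spikes) dim(spikes$waveforms)[1L]

#' Subset a spike set by spike index
#' @param spikes A [spike_set()].
#' @param idx Integer or logical index over spikes.
#' @return A [spike_set()] with the selected spikes, order preserved.
#' @export
subset_spikes <- function(spikes, idx) {
  if (is.logical(idx)) idx <- which(idx)
  w <- spikes$waveforms[idx, , , drop = FALSE]
  structure(
    list(
      waveforms = w,
      trigger_times = spikes$trigger_times[idx],
      trigger_channels = spikes$trigger_channels[idx],
      source_id = spikes$source_id
    ),
    class = "spike_set"
  )
}

# Concatenate each spike's channels into one row: n_spikes x (n_channels*32).
# Channel blocks are laid side by side (channel 1 samples 1..32, then
# channel 2, ...), matching how tetrode waveforms are displayed and how the
# matching stage correlates them.
flatten_waveforms <- function(waveforms) {
  if (length(dim(waveforms)) == 2L) return(waveforms)
  d <- dim(waveforms)
  out <- matrix(0, d[1L], d[2L] * d[3L])
  for (ch in seq_len(d[2L])) {
    out[, ((ch - 1L) * d[3L] + 1L):(ch * d[3L])] <- waveforms[, ch, ]
  }
  out
}
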
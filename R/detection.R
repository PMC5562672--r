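#' Spike-detection configuration
#'
#' Controls high-pass filtering, noise estimation and trough-aligned waveform
#' extraction. The extraction threshold is `threshold_multiplier` times the
#' standard deviation of the background noise (4 by default, the conventional
#' setting); the extraction window is `window_before` samples before the
#' triggering local minimum plus `window_after` after it, 10 + 1 + 21 = 32
#' samples (about 1 ms at 30 kHz) by default, with the trigger at local
#' sample 11.
#'
#' @param threshold_multiplier Threshold in units of noise SD (default 4).
#' @param window_before,window_after Samples before/after the trigger
#'   (defaults 10 and 21; the window is `window_before + 1 + window_after`).
#' @param dead_time Minimum separation in samples enforced between detected
#'   events on one channel (default 0: adjacent qualifying minima are all
#'   extracted, which the overlap-resolution stage relies on).
#' @param noise_estimator `"robust"` (median absolute value / 0.6745,
#'   insensitive to the spikes themselves) or `"plain"` (sample SD).
#' @param highpass_cutoff_hz High-pass corner frequency (default 300).
#' @param invert_polarity Set `TRUE` for positive-going spikes; the trace is
#'   negated before trough detection.
#' @param merge_window Cross-channel candidate-merging window in samples for
#'   multi-channel recordings (default 10).
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(threshold_multiplier = 4,
                             window_before = 10L,
                             window_after = 21L,
                             dead_time = 0L,
                             noise_estimator = c("robust", "plain"),
                             highpass_cutoff_hz = 300,
                             invert_polarity = FALSE,
                             merge_window = 10L) {
  stopifnot(threshold_multiplier > 0, window_before >= 0, window_after >= 0)
  structure(
    list(
      threshold_multiplier = threshold_multiplier,
      window_before = as.integer(window_before),
      window_after = as.integer(window_after),
      window_length = as.integer(window_before + 1L + window_after),
      dead_time = as.integer(dead_time),
      noise_estimator = match.arg(noise_estimator),
      highpass_cutoff_hz = highpass_cutoff_hz,
      invert_polarity = invert_polarity,
      merge_window = as.integer(merge_window)
    ),
    class = "detection_config"
  )
}

#' Zero-phase high-pass filter
#'
#' 4th-order Butterworth high-pass applied forward and backward (zero phase
#' lag, magnitude response squared) to every channel.
#'
#' @param rec A [raw_recording()].
#' @param cutoff_hz Corner frequency in Hz; must be below Nyquist.
#' @param order Filter order (default 4).
#' @return A [raw_recording()] of the same shape.
#' @export
highpass <- function(rec, cutoff_hz = 300, order = 4L) {
  nyq <- rec$sampling_rate_hz / 2
  if (cutoff_hz >= nyq) stop("cutoff must be below the Nyquist frequency")
  ba <- signal::butter(order, cutoff_hz / nyq, type = "high")
  zi <- lfilter_zi(ba$b, ba$a)
  npad <- 3L * (max(length(ba$a), length(ba$b)) - 1L)
  out <- rec$samples
  for (ch in seq_len(nrow(out))) {
    out[ch, ] <- filtfilt_cpp(ba$b, ba$a, out[ch, ], zi, npad)
  }
  raw_recording(out, rec$sampling_rate_hz)
}

#' Estimate the background-noise standard deviation
#'
#' The robust mode estimates the noise SD as `median(|x|) / 0.6745`, the
#' scaling that makes the estimator consistent for Gaussian noise; because
#' spikes occupy a small fraction of samples they barely move the median, so
#' no spike-free segmentation is needed. The plain mode is the sample SD.
#'
#' @param rec A [raw_recording()] (already high-pass filtered in the normal
#'   workflow).
#' @param estimator `"robust"` or `"plain"`.
#' @return Numeric vector, one SD in microvolts per channel.
#' @export
estimate_noise_sd <- function(rec, estimator = c("robust", "plain")) {
  estimator <- match.arg(estimator)
  if (ncol(rec$samples) < 1L) stop("empty recording")
  apply(rec$samples, 1L, function(x) {
    if (estimator == "robust") stats::median(abs(x)) / 0.6745 else stats::sd(x)
  })
}

# Steady-state initial conditions of a direct-form-II-transposed filter: the
# internal state that makes a unit step input produce its steady output from
# the first sample. Used to scale the initial state of each filtfilt pass.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a0 <- a[1L]
  a <- c(a, rep(0, n - length(a))) / a0
  b <- c(b, rep(0, n - length(b))) / a0
  if (n == 1L) return(numeric(0))
  A <- rbind(-a[2:n], cbind(diag(n - 2L), 0))
  if (n == 2L) A <- matrix(-a[2L], 1L, 1L)
  B <- b[2:n] - a[2:n] * b[1L]
  solve(diag(n - 1L) - t(A), B)
}

# Strict local minima of v at or below -threshold; returns 1-based indices.
qualifying_minima <- function(v, threshold) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  idx <- i[v[i] < v[i - 1L] & v[i] < v[i + 1L] & v[i] <= -threshold]
  idx
}

# Candidate troughs on every channel merged into events. Candidates closer
# than merge_window samples (across channels) collapse into one event whose
# trigger is the deepest trough in microvolts over all channels.
find_trough_events <- function(samples, thresholds, merge_window,
                               dead_time = 0L) {
  cand_t <- integer(0); cand_ch <- integer(0); cand_v <- numeric(0)
  for (ch in seq_len(nrow(samples))) {
    idx <- qualifying_minima(samples[ch, ], thresholds[ch])
    cand_t <- c(cand_t, idx)
    cand_ch <- c(cand_ch, rep(ch, length(idx)))
    cand_v <- c(cand_v, samples[ch, idx])
  }
  if (length(cand_t) == 0L) {
    return(data.frame(time = integer(0), channel = integer(0),
                      value = numeric(0)))
  }
  o <- order(cand_t)
  cand_t <- cand_t[o]; cand_ch <- cand_ch[o]; cand_v <- cand_v[o]
  if (nrow(samples) > 1L) {
    grp <- cumsum(c(1L, as.integer(diff(cand_t) > merge_window)))
  } else {
    grp <- seq_along(cand_t)
  }
  keep <- vapply(split(seq_along(cand_t), grp), function(ii) {
    ii[which.min(cand_v[ii])]
  }, integer(1))
  ev <- data.frame(time = cand_t[keep], channel = cand_ch[keep],
                   value = cand_v[keep])
  ev <- ev[order(ev$time), , drop = FALSE]
  if (dead_time > 0L && nrow(ev) > 1L) {
    keep <- rep(TRUE, nrow(ev))
    last <- ev$time[1L]
    for (i in 2:nrow(ev)) {
      if (ev$time[i] - last < dead_time) keep[i] <- FALSE else last <- ev$time[i]
    }
    ev <- ev[keep, , drop = FALSE]
  }
  rownames(ev) <- NULL
  ev
}

# Cut window_before..window_after windows around triggers from a multi-channel
# trace. Triggers whose window crosses a boundary are dropped. Windows that
# run past `pad_ok` boundaries are instead zero-padded when pad = TRUE (used
# for synthetic-waveform extraction from short superpositions).
extract_windows <- function(samples, triggers, before, after, pad = FALSE) {
  n <- ncol(samples)
  L <- before + 1L + after
  if (!pad) {
    ok <- triggers > before & triggers + after <= n
    triggers <- triggers[ok]
  } else {
    ok <- rep(TRUE, length(triggers))
  }
  nt <- length(triggers)
  w <- array(0, dim = c(nt, nrow(samples), L))
  if (nt > 0L) {
    rel <- -before:after
    for (ch in seq_len(nrow(samples))) {
      idx <- outer(triggers, rel, "+")
      inside <- idx >= 1L & idx <= n
      vals <- matrix(0, nt, L)
      vals[inside] <- samples[ch, idx[inside]]
      w[, ch, ] <- vals
    }
  }
  list(waveforms = w, kept = ok, triggers = triggers)
}

#' Detect spikes by amplitude thresholding of local minima
#'
#' Identifies strict local minima of the (already high-pass filtered) trace
#' that reach at or below minus the extraction threshold and cuts a 32-sample
#' window around each, aligned with the trough at local sample 11. On
#' multi-channel recordings the threshold is evaluated per channel and
#' candidate events within `cfg$merge_window` samples of each other across
#' channels are merged into a single event triggered by the deepest trough;
#' the same window is then cut from all channels. Events whose window would
#' cross a recording boundary are discarded.
#'
#' @param rec A high-pass filtered [raw_recording()].
#' @param cfg A [detection_config()].
#' @param threshold_uV Optional explicit threshold(s) in microvolts (one value
#'   or one per channel); when omitted it is `cfg$threshold_multiplier` times
#'   the per-channel noise SD from [estimate_noise_sd()].
#' @return A [spike_set()]; attributes `threshold_uV` (per channel) and
#'   `n_boundary_discarded` record the threshold used and the number of
#'   boundary-discarded events.
#' @export
detect_spikes <- function(rec, cfg = detection_config(), threshold_uV = NULL) {
  samples <- rec$samples
  if (cfg$invert_polarity) samples <- -samples
  if (is.null(threshold_uV)) {
    threshold_uV <- cfg$threshold_multiplier *
      estimate_noise_sd(raw_recording(samples, rec$sampling_rate_hz),
                        cfg$noise_estimator)
  }
  thresholds <- rep_len(threshold_uV, nrow(samples))
  ev <- find_trough_events(samples, thresholds, cfg$merge_window,
                           cfg$dead_time)
  ext <- extract_windows(samples, ev$time, cfg$window_before, cfg$window_after)
  spikes <- spike_set(
    if (cfg$invert_polarity) -ext$waveforms else ext$waveforms,
    ext$triggers,
    trigger_channels = ev$channel[ext$kept],
    source_id = "detect_spikes"
  )
  attr(spikes, "threshold_uV") <- thresholds
  attr(spikes, "n_boundary_discarded") <- sum(!ext$kept)
  spikes
}
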
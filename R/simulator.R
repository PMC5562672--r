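#' Parametric biphasic spike template
#'
#' Difference-of-Gaussians action-potential shape sampled on a 32-point
#' window: a negative trough of `depth_uV` microvolts exactly at sample 11
#' (the trigger point) followed by a slower positive afterpotential. For
#' multi-channel (tetrode) templates, `channel_profile` scales the shape per
#' channel, emulating a unit's distance to each wire.
#'
#' @param unit_id Integer unit id carried by the template.
#' @param depth_uV Trough depth in microvolts (positive number).
#' @param trough_sd Trough width (Gaussian SD, samples; default 1.6).
#' @param peak_frac Afterpotential amplitude as a fraction of the trough
#'   depth (default 0.35).
#' @param peak_lag Afterpotential delay after the trough (samples, default 6).
#' @param peak_sd Afterpotential width (samples, default 4).
#' @param channel_profile Per-channel amplitude multipliers (default 1, a
#'   single channel).
#' @return A `template` object (`unit_id`, `waveform`, `trigger_index = 11`).
#' @export
make_template <- function(unit_id, depth_uV, trough_sd = 1.6,
                          peak_frac = 0.35, peak_lag = 6, peak_sd = 4,
                          channel_profile = 1) {
  t <- 1:32
  base <- -depth_uV * exp(-(t - 11)^2 / (2 * trough_sd^2)) +
    peak_frac * depth_uV * exp(-(t - 11 - peak_lag)^2 / (2 * peak_sd^2))
  w <- outer(channel_profile, base)
  structure(
    list(unit_id = as.integer(unit_id), waveform = w, trigger_index = 11L,
         source_clusters = integer(0), member_index = integer(0),
         quality = list(isolation = NA_real_, isi_fraction = 0,
                        n_members = 0L)),
    class = "template"
  )
}

# Preset template sets: two distinct single-electrode units; three tetrode
# units with distinct per-channel amplitude profiles.
electrode_sim_templates <- function() {
  list(
    make_template(1L, depth_uV = 150, trough_sd = 1.5, peak_frac = 0.40,
                  peak_lag = 5, peak_sd = 3.5),
    make_template(2L, depth_uV = 100, trough_sd = 2.2, peak_frac = 0.25,
                  peak_lag = 8, peak_sd = 5)
  )
}

tetrode_sim_templates <- function() {
  list(
    make_template(1L, depth_uV = 150, trough_sd = 1.5, peak_frac = 0.40,
                  peak_lag = 5, peak_sd = 3.5,
                  channel_profile = c(1, 0.6, 0.3, 0.15)),
    make_template(2L, depth_uV = 130, trough_sd = 2.2, peak_frac = 0.25,
                  peak_lag = 8, peak_sd = 5,
                  channel_profile = c(0.2, 1, 0.55, 0.3)),
    make_template(3L, depth_uV = 110, trough_sd = 1.9, peak_frac = 0.33,
                  peak_lag = 6, peak_sd = 4.5,
                  channel_profile = c(0.3, 0.15, 0.65, 1))
  )
}

#' Simulation configuration
#'
#' Describes one synthetic raw dataset: a set of unit templates driven by
#' independent surrogate spike trains with refractory recovery, plus
#' composite noise built from many scaled-down surrogate trains of
#' spike-shaped waveforms. Defaults follow the generation recipe this
#' workflow is evaluated on: 30-min, 30-kHz recordings, unit free rates drawn
#' uniformly from [0, 20] spikes/s, noise built from 1000 trains with free
#' rates uniform on [0, 200] spikes/s; the recovery function is a sigmoid of
#' the time since the last spike (center 2 ms, width 1 ms) with a hard floor
#' of 1 ms below which no spike can follow another.
#'
#' @param preset `"electrode"` (2 single-channel templates) or `"tetrode"`
#'   (3 four-channel templates); ignored when `templates` is given.
#' @param duration_s Recording length in seconds (default 1800).
#' @param sampling_rate_hz Sampling rate (default 30000).
#' @param templates Optional list of `template` objects.
#' @param free_rate_range Uniform range for unit free-firing rates, spikes/s.
#' @param recovery List with `center_ms`, `width_ms`, `hard_floor_ms`.
#' @param noise_n_trains Number of noise surrogate trains (default 1000).
#' @param noise_rate_range Uniform range for noise-train free rates.
#' @param noise_pool Optional list of waveform matrices used to render noise
#'   events; defaults to the templates plus scaled and pairwise-summed
#'   variants (emulating the mix of single-unit, multi-unit and overlapping
#'   shapes in a recording).
#' @param snr Trough signal-to-noise ratio: the smallest unit's
#'   deepest-channel trough depth divided by the noise SD (default 10);
#'   ignored when `target_noise_sd_uV` is given.
#' @param target_noise_sd_uV Explicit noise SD in microvolts.
#' @param seed RNG seed; the simulation is bit-reproducible given the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(preset = c("electrode", "tetrode"),
                       duration_s = 1800, sampling_rate_hz = 30000,
                       templates = NULL,
                       free_rate_range = c(0, 20),
                       recovery = list(center_ms = 2, width_ms = 1,
                                       hard_floor_ms = 1),
                       noise_n_trains = 1000L,
                       noise_rate_range = c(0, 200),
                       noise_pool = NULL,
                       snr = 10, target_noise_sd_uV = NULL,
                       seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(templates)) {
    templates <- switch(preset,
                        electrode = electrode_sim_templates(),
                        tetrode = tetrode_sim_templates())
  }
  if (is.null(target_noise_sd_uV)) {
    depths <- vapply(templates, function(tp) max(-apply(tp$waveform, 1, min)), 0)
    target_noise_sd_uV <- min(depths) / snr
  }
  if (is.null(noise_pool)) noise_pool <- default_noise_pool(templates)
  stopifnot(duration_s > 0, sampling_rate_hz > 0,
            all(free_rate_range >= 0), all(noise_rate_range >= 0))
  structure(
    list(preset = preset, duration_s = duration_s,
         sampling_rate_hz = sampling_rate_hz, templates = templates,
         free_rate_range = free_rate_range, recovery = recovery,
         noise_n_trains = as.integer(noise_n_trains),
         noise_rate_range = noise_rate_range, noise_pool = noise_pool,
         target_noise_sd_uV = target_noise_sd_uV, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# templates + attenuated and pairwise-summed variants, standing in for the
# mix of single-unit, multi-unit and overlapping shapes among a recording's
# extracted waveforms; the noise construction normalizes amplitude away.
default_noise_pool <- function(templates) {
  pool <- lapply(templates, function(tp) tp$waveform)
  pool <- c(pool, lapply(templates, function(tp) 0.5 * tp$waveform))
  if (length(templates) >= 2L) {
    for (i in seq_len(length(templates) - 1L)) {
      for (j in (i + 1L):length(templates)) {
        for (d in c(0L, 8L, 16L)) {
          sp <- superpose(templates[[i]], templates[[j]], d)
          tr <- which.min(sp$waveform[which.max(rowSums(sp$waveform^2)), ])
          win <- extract_windows(sp$waveform, tr, 10L, 21L, pad = TRUE)
          pool[[length(pool) + 1L]] <-
            matrix(win$waveforms[1L, , ], nrow = nrow(sp$waveform))
        }
      }
    }
  }
  pool
}

#' Surrogate spike train with refractory recovery
#'
#' Draws a free firing rate uniformly from `free_rate_range` (unless `rate_hz`
#' is given), generates a homogeneous candidate process at that rate, and
#' thins it sequentially: a candidate at delay `dt` since the last accepted
#' spike survives with probability `1 / (1 + exp(-(dt - center) / width))`,
#' and never when `dt` is below the hard floor. The result exhibits a
#' realistic relative refractory period rather than Poisson statistics.
#'
#' @param duration_s Train length in seconds.
#' @param cfg A [sim_config()] (recovery parameters and rate range).
#' @param rate_hz Optional fixed free rate in spikes/s.
#' @return Sorted spike times in seconds; attribute `free_rate_hz` records
#'   the rate drawn. Uses the current RNG stream.
#' @export
surrogate_train <- function(duration_s, cfg = sim_config(), rate_hz = NULL) {
  if (is.null(rate_hz)) {
    rate_hz <- stats::runif(1, cfg$free_rate_range[1], cfg$free_rate_range[2])
  }
  n_cand <- stats::rpois(1, rate_hz * duration_s)
  if (n_cand == 0) {
    out <- numeric(0)
    attr(out, "free_rate_hz") <- rate_hz
    return(out)
  }
  cand <- sort(stats::runif(n_cand, 0, duration_s))
  u <- stats::runif(n_cand)
  out <- thin_train_cpp(cand, u,
                        cfg$recovery$center_ms / 1000,
                        cfg$recovery$width_ms / 1000,
                        cfg$recovery$hard_floor_ms / 1000)
  attr(out, "free_rate_hz") <- rate_hz
  out
}

#' Render spike trains as a voltage trace
#'
#' Places each unit's template on a zero trace with the template's trigger
#' sample (local sample 11) at the spike's sample time; overlapping
#' contributions add linearly. Spikes whose 32-sample footprint would cross
#' the recording edge are skipped with a warning.
#'
#' @param trains List of spike-time vectors in seconds, one per template.
#' @param templates List of `template` objects, aligned with `trains`.
#' @param duration_s Trace length in seconds.
#' @param sampling_rate_hz Sampling rate.
#' @return List: `recording` (a [raw_recording()]), `unit_times` (list of
#'   integer sample times actually rendered, per unit).
#' @export
render_signal <- function(trains, templates, duration_s, sampling_rate_hz) {
  stopifnot(length(trains) == length(templates))
  n_samp <- as.integer(round(duration_s * sampling_rate_hz))
  nch <- nrow(templates[[1L]]$waveform)
  trace <- matrix(0, nch, n_samp)
  unit_times <- vector("list", length(trains))
  n_skipped <- 0L
  for (u in seq_along(trains)) {
    t_samp <- as.integer(round(trains[[u]] * sampling_rate_hz))
    ok <- t_samp >= 11L & t_samp <= n_samp - 21L
    n_skipped <- n_skipped + sum(!ok)
    t_samp <- t_samp[ok]
    unit_times[[u]] <- t_samp
    if (length(t_samp) == 0L) next
    for (ch in seq_len(nch)) {
      pool <- matrix(templates[[u]]$waveform[ch, ], ncol = 1L)
      trace[ch, ] <- render_events_cpp(trace[ch, ], t_samp,
                                       rep(1L, length(t_samp)), pool, 11L)
    }
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " spike(s) too close to the recording edge; skipped")
  }
  list(recording = raw_recording(trace, sampling_rate_hz),
       unit_times = unit_times)
}

#' Composite spike-derived noise
#'
#' Builds `cfg$noise_n_trains` surrogate trains with free rates uniform on
#' `cfg$noise_rate_range`, replaces every spike with a waveform drawn
#' uniformly from the noise pool, and sums the trains. The summed signal is
#' mean-subtracted, normalized to a maximum absolute amplitude of exactly
#' 1 microvolt (per channel), and finally multiplied by an amplification
#' factor so its standard deviation equals `cfg$target_noise_sd_uV`.
#'
#' @param cfg A [sim_config()].
#' @param duration_s Noise length in seconds (defaults to `cfg$duration_s`).
#' @return List: `trace` (`n_channels x n_samples` matrix in microvolts),
#'   `normalized` (the max-1 pre-amplification trace),
#'   `amplification` (per-channel scale factor applied).
#' @export
make_noise <- function(cfg, duration_s = cfg$duration_s) {
  n_samp <- as.integer(round(duration_s * cfg$sampling_rate_hz))
  pool <- cfg$noise_pool
  nch <- nrow(pool[[1L]])
  pool_mats <- lapply(seq_len(nch), function(ch) {
    sapply(pool, function(w) w[ch, ])
  })
  trace <- matrix(0, nch, n_samp)
  chunk <- 50L
  done <- 0L
  while (done < cfg$noise_n_trains) {
    m <- min(chunk, cfg$noise_n_trains - done)
    times <- integer(0); ids <- integer(0)
    for (k in seq_len(m)) {
      rate <- stats::runif(1, cfg$noise_rate_range[1], cfg$noise_rate_range[2])
      tr <- surrogate_train(duration_s, cfg, rate_hz = rate)
      t_samp <- as.integer(round(tr * cfg$sampling_rate_hz))
      t_samp <- t_samp[t_samp >= 11L & t_samp <= n_samp - 21L]
      times <- c(times, t_samp)
      ids <- c(ids, sample.int(length(pool), length(t_samp), replace = TRUE))
    }
    if (length(times)) {
      for (ch in seq_len(nch)) {
        trace[ch, ] <- render_events_cpp(trace[ch, ], times, ids,
                                         pool_mats[[ch]], 11L)
      }
    }
    done <- done + m
  }
  if (all(trace == 0)) stop("degenerate all-zero noise signal")
  trace <- trace - rowMeans(trace)
  peak <- apply(abs(trace), 1L, max)
  normalized <- trace / peak
  sds <- apply(normalized, 1L, stats::sd)
  amplification <- cfg$target_noise_sd_uV / sds
  list(trace = normalized * amplification, normalized = normalized,
       amplification = amplification)
}

#' Simulate a raw recording with ground truth
#'
#' Generates one surrogate train per template, renders the signal, adds
#' composite noise, and returns the recording together with per-unit ground
#' truth. A truth spike is flagged as an overlap when any other unit fired
#' within strictly less than 1 ms of it (flags are symmetric across the pair).
#' Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_result`: `recording`, `truth` (list with
#'   `unit_times`, `overlap_flags`, `sampling_rate_hz`), `config`.
#' @export
simulate_recording <- function(cfg) {
  set.seed(cfg$seed)
  trains <- lapply(cfg$templates, function(tp) {
    surrogate_train(cfg$duration_s, cfg)
  })
  sig <- render_signal(trains, cfg$templates, cfg$duration_s,
                       cfg$sampling_rate_hz)
  noise <- make_noise(cfg)
  rec <- raw_recording(sig$recording$samples + noise$trace,
                       cfg$sampling_rate_hz)
  flags <- overlap_flags(sig$unit_times, cfg$sampling_rate_hz)
  structure(
    list(recording = rec,
         truth = list(unit_times = sig$unit_times, overlap_flags = flags,
                      sampling_rate_hz = cfg$sampling_rate_hz),
         config = cfg),
    class = "sim_result"
  )
}

# flag truth spikes with a cross-unit neighbour closer than 1 ms
overlap_flags <- function(unit_times, sampling_rate_hz) {
  win <- sampling_rate_hz / 1000  # 1 ms in samples
  lapply(seq_along(unit_times), function(u) {
    t_u <- unit_times[[u]]
    if (length(t_u) == 0L) return(logical(0))
    others <- sort(unlist(unit_times[-u]))
    if (length(others) == 0L) return(rep(FALSE, length(t_u)))
    pos <- findInterval(t_u, others)
    d_lo <- ifelse(pos >= 1L, t_u - others[pmax(pos, 1L)], Inf)
    d_hi <- ifelse(pos < length(others), others[pmin(pos + 1L, length(others))] - t_u, Inf)
    pmin(d_lo, d_hi, na.rm = TRUE) < win
  })
}
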
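#' Superpose two single-unit templates at a phase shift
#'
#' Point-by-point sum of two 32-sample templates with the second delayed by
#' `d` samples. The result has `32 + d` samples per channel: template `a`
#' occupies samples 1..32 (trigger at sample 11), template `b` occupies
#' samples `d+1 .. d+32` (trigger at sample `11 + d`); the templates add
#' where they overlap and stand alone elsewhere. Superposition lengths thus
#' range from 32 (complete overlap, `d = 0`) to 63 (`d = 31`, a single shared
#' sample).
#'
#' @param a,b `template` objects with equal channel counts.
#' @param d Integer shift in samples, `0 <= d <= 31`.
#' @return A list of class `superposition`: `pair` (unit ids, `a` leading),
#'   `shift`, `waveform` (`n_channels x (32 + d)`), `trigger_a` (11),
#'   `trigger_b` (`11 + d`).
#' @export
superpose <- function(a, b, d) {
  L <- ncol(a$waveform)
  if (d < 0 || d > L - 1) stop("shift d must be in 0..", L - 1)
  if (nrow(a$waveform) != nrow(b$waveform)) {
    stop("templates must have equal channel counts")
  }
  nch <- nrow(a$waveform)
  w <- matrix(0, nch, L + d)
  w[, 1:L] <- a$waveform
  w[, (d + 1L):(d + L)] <- w[, (d + 1L):(d + L)] + b$waveform
  structure(
    list(pair = c(a$unit_id, b$unit_id), shift = as.integer(d),
         waveform = w, trigger_a = 11L, trigger_b = 11L + as.integer(d)),
    class = "superposition"
  )
}

#' Extract synthetic waveforms from a superposition
#'
#' Applies the same amplitude-thresholding rule used for real spikes to a
#' superposition waveform: every strict local minimum at or below minus the
#' extraction threshold triggers a 32-sample window (10 samples before the
#' trough, 21 after). Windows extending past the superposition boundary are
#' zero-padded, the superposition being embedded in a zero baseline. The
#' positions of the two parent-template trigger points are recorded relative
#' to each synthetic window (local sample indices, possibly outside 1..32).
#'
#' @param sp A [superpose()] result.
#' @param threshold_uV Extraction threshold(s) in microvolts, the same value
#'   used for real-spike extraction (one per channel).
#' @param cfg A [detection_config()] (window geometry and merge rule).
#' @return List of `synthetic_waveform` objects: `waveform`
#'   (`n_channels x 32`), `pair`, `shift`, `trigger_in_superposition`,
#'   `parent_trigger_offsets` (local positions of the two parent triggers),
#'   `trigger_channel`.
#' @export
extract_synthetics <- function(sp, threshold_uV, cfg = detection_config()) {
  thresholds <- rep_len(threshold_uV, nrow(sp$waveform))
  ev <- find_trough_events(sp$waveform, thresholds, cfg$merge_window,
                           cfg$dead_time)
  if (nrow(ev) == 0L) return(list())
  ext <- extract_windows(sp$waveform, ev$time, cfg$window_before,
                         cfg$window_after, pad = TRUE)
  lapply(seq_along(ext$triggers), function(i) {
    t0 <- ext$triggers[i]
    win_start <- t0 - cfg$window_before
    structure(
      list(
        waveform = matrix(ext$waveforms[i, , ], nrow = nrow(sp$waveform)),
        pair = sp$pair,
        shift = sp$shift,
        trigger_in_superposition = t0,
        parent_trigger_offsets = c(sp$trigger_a - win_start + 1L,
                                   sp$trigger_b - win_start + 1L),
        trigger_channel = ev$channel[i]
      ),
      class = "synthetic_waveform"
    )
  })
}

#' Generate the synthetic-waveform bank
#'
#' For every unordered pair of distinct templates, builds superpositions at
#' all phase shifts - `a` leading `b` by 0..31 samples and `b` leading `a` by
#' 1..31 (the zero shift counted once), 63 superpositions per pair - and
#' extracts synthetic waveforms from each with the real-spike threshold.
#' Exact-duplicate synthetics arising from the same pair are removed, keeping
#' the lowest id. Self-pairs are excluded: two same-unit spikes under 1 ms
#' apart would violate the refractory period the pipeline later enforces.
#'
#' @param templates List of at least two `template` objects.
#' @param threshold_uV Extraction threshold(s) in microvolts.
#' @param cfg A [detection_config()].
#' @return A `synthetic_bank`: `waveforms` (`n x n_channels x 32` array) and
#'   `meta` (data frame: `id`, `unit_a`, `unit_b`, `shift`,
#'   `trigger_in_superposition`, `offset_a`, `offset_b`, `trigger_channel`).
#' @export
generate_bank <- function(templates, threshold_uV, cfg = detection_config()) {
  if (length(templates) < 2L) stop("need at least 2 templates")
  syn <- list()
  pair_rows <- list()
  for (i in seq_len(length(templates) - 1L)) {
    for (j in (i + 1L):length(templates)) {
      pair_syn <- list()
      n_sup <- 0L
      for (d in 0:31) {
        pair_syn <- c(pair_syn, extract_synthetics(
          superpose(templates[[i]], templates[[j]], d), threshold_uV, cfg))
        n_sup <- n_sup + 1L
      }
      for (d in 1:31) {
        pair_syn <- c(pair_syn, extract_synthetics(
          superpose(templates[[j]], templates[[i]], d), threshold_uV, cfg))
        n_sup <- n_sup + 1L
      }
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        unit_i = templates[[i]]$unit_id, unit_j = templates[[j]]$unit_id,
        n_superpositions = n_sup)
      if (length(pair_syn) > 1L) {
        keys <- vapply(pair_syn, function(s) {
          paste(signif(as.vector(s$waveform), 12), collapse = ",")
        }, character(1))
        pair_syn <- pair_syn[!duplicated(keys)]
      }
      syn <- c(syn, pair_syn)
    }
  }
  if (length(syn) == 0L) {
    stop("no synthetic waveforms crossed the threshold")
  }
  nch <- nrow(syn[[1L]]$waveform)
  L <- ncol(syn[[1L]]$waveform)
  w <- array(0, dim = c(length(syn), nch, L))
  for (i in seq_along(syn)) w[i, , ] <- syn[[i]]$waveform
  meta <- data.frame(
    id = seq_along(syn),
    unit_a = vapply(syn, function(s) s$pair[1L], 0),
    unit_b = vapply(syn, function(s) s$pair[2L], 0),
    shift = vapply(syn, function(s) s$shift, 0L),
    trigger_in_superposition =
      vapply(syn, function(s) s$trigger_in_superposition, 0L),
    offset_a = vapply(syn, function(s) s$parent_trigger_offsets[1L], 0L),
    offset_b = vapply(syn, function(s) s$parent_trigger_offsets[2L], 0L),
    trigger_channel = vapply(syn, function(s) s$trigger_channel, 0L)
  )
  structure(list(waveforms = w, meta = meta,
                 pairs = do.call(rbind, pair_rows)),
            class = "synthetic_bank")
}

#' @export
print.synthetic_bank <- function(x, ...) {
  cat(sprintf("<synthetic_bank> %d synthetic waveforms from %d template pair(s)\n",
              nrow(x$meta), nrow(x$pairs)))
  invisible(x)
}
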
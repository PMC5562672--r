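#' Classify the assignment scenario of a matched overlap
#'
#' Three scenarios govern how a matched overlapping waveform is converted
#' into unit spikes, driven by where the two parent-template trigger points
#' of the best-matching synthetic waveform fall:
#'
#' * Scenario 1 - exactly one parent trigger lies inside the synthetic's
#'   32-sample window: the units fired far apart, the out-of-window template
#'   contributed only a tail, and the spike belongs to the in-window unit
#'   alone.
#' * Both parent triggers inside: the count of strict local minima at or
#'   below minus the extraction threshold in the real waveform (trigger
#'   channel) decides - one minimum means the spikes fused into a single
#'   trough (Scenario 2, assign to both units); two or more mean the partner
#'   trough was extracted as its own spike (Scenario 3, assign to one unit).
#'   Scenario 2 additionally requires the matched synthetic itself to show a
#'   single threshold-crossing minimum: when the noise-free synthetic
#'   displays two troughs but the recorded waveform shows one, the fused
#'   two-unit reading is inconsistent with the waveform and the spike is
#'   assigned as Scenario 3 (fused single-minimum superpositions only arise
#'   at small phase shifts).
#'
#' The degenerate case of both parent triggers outside the window is logged
#' and classified as Scenario 1 with the nearer parent dominant.
#'
#' @param match_row One row of a [best_match()] data frame (must have a
#'   synthetic match).
#' @param bank The [generate_bank()] result.
#' @param spike_waveform The real spike's `n_channels x 32` waveform matrix.
#' @param trigger_channel Channel whose trough triggered the spike (kept for
#'   provenance; minima are counted across channels).
#' @param threshold_uV Extraction threshold(s), as used in detection.
#' @param trigger_time Absolute trigger time of the spike (samples); needed
#'   for the separate-extraction check.
#' @param all_trigger_times Optional sorted vector of every detected trigger
#'   time in the recording. When provided, a Scenario-3 classification is
#'   kept only if another detection exists within the 32-sample window -
#'   the premise of Scenario 3 is that the partner trough was extracted as
#'   its own spike. When detection merged both troughs into one event (the
#'   cross-channel merge rule can do this), no separate partner spike exists
#'   and the waveform is assigned to both units as Scenario 2.
#' @param merge_window Cross-channel merge window used for minima counting
#'   (default 10, as in detection).
#' @return Integer scenario 1, 2 or 3, with attribute `dominant` (1 or 2,
#'   which parent is in-window / nearer) for Scenario 1.
#' @export
classify_scenario <- function(match_row, bank, spike_waveform,
                              trigger_channel = 1L, threshold_uV,
                              trigger_time = NULL, all_trigger_times = NULL,
                              merge_window = 10L) {
  stopifnot(!is.na(match_row$synthetic_id))
  meta <- bank$meta[bank$meta$id == match_row$synthetic_id, ]
  offs <- c(meta$offset_a, meta$offset_b)
  inside <- offs >= 1L & offs <= 32L
  if (sum(inside) == 1L) {
    return(structure(1L, dominant = which(inside)))
  }
  if (sum(inside) == 0L) {
    warning("both parent triggers outside the synthetic window; ",
            "treating as Scenario 1 with the nearer parent dominant")
    return(structure(1L, dominant = which.min(abs(offs - 11L))))
  }
  thr <- rep_len(threshold_uV, nrow(spike_waveform))
  n_events <- function(wf) {
    nrow(find_trough_events(wf, thr, merge_window))
  }
  nmin <- n_events(spike_waveform)
  syn_row <- which(bank$meta$id == match_row$synthetic_id)
  syn_wf <- matrix(bank$waveforms[syn_row, , ],
                   nrow = dim(bank$waveforms)[2L])
  sc <- if (nmin >= 2L || n_events(syn_wf) >= 2L) 3L else 2L
  if (sc == 3L && !is.null(all_trigger_times) && !is.null(trigger_time)) {
    near <- all_trigger_times[abs(all_trigger_times - trigger_time) <= 21L]
    if (length(near) < 2L) sc <- 2L   # no separately extracted partner
  }
  sc
}

#' Convert a matched overlap into unit assignments
#'
#' Scenario 1 assigns the spike to the in-window (dominant) unit at the
#' spike's trigger time. Scenario 2 assigns it to both units; each unit's
#' spike time is the trigger time plus that unit's parent-trigger offset
#' minus 11, so the two reconstructed troughs sit where the parent templates
#' placed them. Scenario 3 assigns the single unit whose parent trigger is
#' nearest the synthetic's trigger (local sample 11), at the spike's trigger
#' time; an exact tie goes to the unit with the deeper template trough.
#'
#' When the real waveform and thresholds are supplied, each Scenario-2 unit
#' is corroborated against the recording: the recorded voltage at that
#' unit's reconstructed trough position, on the channel where the unit's
#' template is deepest, must reach the extraction threshold - the same
#' criterion that admits spikes in the first place. A claimed constituent
#' whose trough position shows no threshold-crossing deflection is dropped,
#' and the waveform is assigned to the corroborated unit(s) only.
#'
#' @param match_row One row of [best_match()] output.
#' @param scenario Result of [classify_scenario()].
#' @param bank The [generate_bank()] result.
#' @param trigger_time Absolute trigger time (samples) of the real spike.
#' @param templates The template list (for the Scenario-3 tie-break and the
#'   per-unit dominant channel).
#' @param spike_waveform Optional `n_channels x 32` waveform matrix of the
#'   real spike (enables the Scenario-2 corroboration check).
#' @param threshold_uV Optional extraction threshold(s), one per channel.
#' @return A list of class `assignment`: `spike_index`, `scenario`,
#'   `assigned_units`, `assigned_times` (one time per assigned unit).
#' @export
assign_overlap <- function(match_row, scenario, bank, trigger_time,
                           templates = NULL, spike_waveform = NULL,
                           threshold_uV = NULL) {
  meta <- bank$meta[bank$meta$id == match_row$synthetic_id, ]
  units <- c(meta$unit_a, meta$unit_b)
  offs <- c(meta$offset_a, meta$offset_b)
  sc <- as.integer(scenario)
  if (sc == 1L) {
    dom <- attr(scenario, "dominant")
    if (is.null(dom)) dom <- which(offs >= 1L & offs <= 32L)[1L]
    out_units <- units[dom]
    out_times <- trigger_time
  } else if (sc == 2L) {
    keep <- c(TRUE, TRUE)
    if (!is.null(spike_waveform) && !is.null(threshold_uV) &&
        !is.null(templates)) {
      thr <- rep_len(threshold_uV, nrow(spike_waveform))
      for (k in 1:2) {
        ch <- which.min(apply(templates[[units[k]]]$waveform, 1L, min))
        pos <- offs[k]
        if (pos >= 1L && pos <= ncol(spike_waveform)) {
          keep[k] <- spike_waveform[ch, pos] <= -thr[ch]
        }
      }
    }
    if (sum(keep) == 1L) {
      # downgraded to a single-unit assignment (reported as Scenario 3)
      return(structure(
        list(spike_index = match_row$spike_index, scenario = 3L,
             assigned_units = units[keep],
             assigned_times = trigger_time + (offs[keep] - 11L)),
        class = "assignment"
      ))
    }
    if (sum(keep) == 0L) {
      pick <- which.min(abs(offs - 11L))
      return(structure(
        list(spike_index = match_row$spike_index, scenario = 3L,
             assigned_units = units[pick], assigned_times = trigger_time),
        class = "assignment"
      ))
    }
    out_units <- units
    out_times <- trigger_time + (offs - 11L)
  } else {
    dist <- abs(offs - 11L)
    if (dist[1L] == dist[2L] && !is.null(templates)) {
      troughs <- vapply(units, function(u) min(templates[[u]]$waveform), 0)
      pick <- which.min(troughs)
    } else {
      pick <- which.min(dist)
    }
    out_units <- units[pick]
    out_times <- trigger_time
  }
  structure(
    list(spike_index = match_row$spike_index, scenario = sc,
         assigned_units = out_units, assigned_times = out_times),
    class = "assignment"
  )
}

#' Enforce the refractory period on assigned units
#'
#' Scans each unit's spikes chronologically; whenever two consecutive spikes
#' are closer than the refractory period, the one whose waveform correlates
#' less with the unit's mean waveform is demoted to the multi-unit pool, and
#' the scan repeats until no violation remains. After cleanup no unit
#' contains an inter-spike interval below the refractory period.
#'
#' @param unit_events List (one element per unit) of data frames with columns
#'   `time` (samples) and `r_to_mean` (Pearson correlation of the spike's
#'   waveform with the unit mean waveform); extra columns are carried along.
#' @param sampling_rate_hz Sampling rate.
#' @param refractory_ms Refractory period in milliseconds (default 1).
#' @return List: `units` (cleaned data frames, chronological) and `demoted`
#'   (data frame of removed events with their unit ids).
#' @export
refractory_cleanup <- function(unit_events, sampling_rate_hz,
                               refractory_ms = 1.0) {
  refr <- refractory_ms / 1000 * sampling_rate_hz
  demoted <- list()
  cleaned <- vector("list", length(unit_events))
  for (u in seq_along(unit_events)) {
    df <- unit_events[[u]]
    df <- df[order(df$time), , drop = FALSE]
    repeat {
      if (nrow(df) < 2L) break
      gap <- diff(df$time)
      v <- which(gap < refr)
      if (length(v) == 0L) break
      i <- v[1L]
      drop_row <- if (df$r_to_mean[i] <= df$r_to_mean[i + 1L]) i else i + 1L
      dem <- df[drop_row, , drop = FALSE]
      dem$unit <- u
      demoted[[length(demoted) + 1L]] <- dem
      df <- df[-drop_row, , drop = FALSE]
    }
    rownames(df) <- NULL
    cleaned[[u]] <- df
  }
  list(
    units = cleaned,
    demoted = if (length(demoted)) do.call(rbind, demoted) else
      data.frame(time = numeric(0), r_to_mean = numeric(0), unit = integer(0))
  )
}
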
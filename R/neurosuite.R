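#' Write Neurosuite-style sorting files
#'
#' Emits the classic `.fet.N` / `.clu.N` / `.res.N` / `.spk.N` quartet used by
#' the KlustaKwik / Klusters ecosystem so results can be inspected or
#' re-clustered with those tools. `.fet` holds the feature count on its first
#' line then one integer-rounded feature row per spike; `.clu` holds the
#' number of distinct labels then one label per line; `.res` one trigger time
#' (samples) per line; `.spk` int16 waveform samples, channel-interleaved per
#' sample within each spike.
#'
#' @param basepath Output path prefix; files are written as
#'   `<basepath>.fet.<shank>` etc.
#' @param spikes Optional [spike_set()].
#' @param features Optional numeric feature matrix (`n_spikes x n_features`).
#' @param labels Optional integer label vector (0 = unsorted/multi-unit by
#'   convention).
#' @param shank Electrode-group number appended to each extension (default 1).
#' @return Character vector of the files written, invisibly.
#' @export
write_neurosuite <- function(basepath, spikes = NULL, features = NULL,
                             labels = NULL, shank = 1L) {
  counts <- c(
    if (!is.null(spikes)) n_spikes(spikes),
    if (!is.null(features)) nrow(features),
    if (!is.null(labels)) length(labels)
  )
  if (length(counts) == 0L) stop("nothing to write")
  if (length(unique(counts)) != 1L) {
    stop("spikes, features and labels disagree on the number of items")
  }
  written <- character(0)
  if (!is.null(features)) {
    p <- sprintf("%s.fet.%d", basepath, shank)
    con <- file(p, "w")
    writeLines(as.character(ncol(features)), con)
    utils::write.table(round(features), con, row.names = FALSE,
                       col.names = FALSE)
    close(con)
    written <- c(written, p)
  }
  if (!is.null(labels)) {
    p <- sprintf("%s.clu.%d", basepath, shank)
    writeLines(c(as.character(length(unique(labels))),
                 as.character(as.integer(labels))), p)
    written <- c(written, p)
  }
  if (!is.null(spikes)) {
    p <- sprintf("%s.res.%d", basepath, shank)
    writeLines(as.character(spikes$trigger_times), p)
    written <- c(written, p)
    p <- sprintf("%s.spk.%d", basepath, shank)
    d <- dim(spikes$waveforms)
    # per spike: samples advance slowest, channels fastest (Neurosuite layout)
    v <- aperm(spikes$waveforms, c(2L, 3L, 1L))
    writeBin(as.integer(round(as.vector(v))), p, size = 2L, endian = "little")
    written <- c(written, p)
  }
  invisible(written)
}

#' Read Neurosuite-style sorting files
#'
#' Reads whichever of `.fet` / `.clu` / `.res` / `.spk` exist under
#' `basepath`; absent components are returned as `NULL`. A `.clu` header that
#' disagrees with the body raises a warning and the body wins; non-monotonic
#' `.res` times are sorted (and the `.spk` waveforms reordered with them) with
#' a warning.
#'
#' @inheritParams write_neurosuite
#' @param n_channels Channel count used to reshape `.spk` (default 1).
#' @param n_window Samples per waveform per channel in `.spk` (default 32).
#' @return A list with components `spikes`, `features`, `labels` (each
#'   possibly `NULL`).
#' @export
read_neurosuite <- function(basepath, shank = 1L, n_channels = 1L,
                            n_window = 32L) {
  fet <- sprintf("%s.fet.%d", basepath, shank)
  clu <- sprintf("%s.clu.%d", basepath, shank)
  res <- sprintf("%s.res.%d", basepath, shank)
  spk <- sprintf("%s.spk.%d", basepath, shank)
  if (!any(file.exists(c(fet, clu, res, spk)))) {
    stop("no Neurosuite files found at ", basepath)
  }
  features <- labels <- spikes <- NULL
  if (file.exists(fet)) {
    ln <- readLines(fet)
    nf <- as.integer(ln[1L])
    features <- matrix(
      scan(text = ln[-1L], quiet = TRUE), ncol = nf, byrow = TRUE
    )
  }
  if (file.exists(clu)) {
    v <- as.integer(readLines(clu))
    labels <- v[-1L]
    if (v[1L] != length(unique(labels))) {
      warning("clu header count disagrees with body; using body")
    }
  }
  times <- NULL
  if (file.exists(res)) {
    times <- as.integer(readLines(res))
  }
  if (file.exists(spk)) {
    if (is.null(times)) stop("cannot read .spk without .res trigger times")
    sz <- file.info(spk)$size
    v <- readBin(spk, "integer", n = sz / 2, size = 2L, signed = TRUE,
                 endian = "little")
    n <- length(times)
    w <- array(as.numeric(v), dim = c(n_channels, n_window, n))
    w <- aperm(w, c(3L, 1L, 2L))
    if (is.unsorted(times, strictly = TRUE)) {
      warning("non-monotonic .res times; sorting on load")
      o <- order(times)
      times <- times[o]
      w <- w[o, , , drop = FALSE]
    }
    spikes <- spike_set(w, times, source_id = basepath)
  } else if (!is.null(times)) {
    if (is.unsorted(times, strictly = TRUE)) {
      warning("non-monotonic .res times; sorting on load")
      times <- sort(times)
    }
    attr(times, "class") <- NULL
  }
  list(spikes = spikes, features = features, labels = labels,
       trigger_times = times)
}

#' Export a sort result as CSV
#'
#' One row per assigned spike: unit id, spike time in samples and seconds, and
#' the provenance of the assignment (`template` for first-pass template
#' cluster members, `scenario1/2/3` for resolved overlaps, `multiunit` for the
#' residual pool).
#'
#' @param result A sort result from [run_sort()].
#' @param path Destination CSV path.
#' @param sampling_rate_hz Sampling rate used to convert samples to seconds.
#' @return `path`, invisibly.
#' @export
export_result_csv <- function(result, path, sampling_rate_hz) {
  rows <- list()
  for (u in seq_along(result$units)) {
    df <- result$units[[u]]
    if (nrow(df) > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        unit = u, time_samples = df$time,
        time_s = df$time / sampling_rate_hz,
        provenance = df$provenance
      )
    }
  }
  if (length(result$multiunit) > 0) {
    rows[[length(rows) + 1L]] <- data.frame(
      unit = 0L, time_samples = result$multiunit,
      time_s = result$multiunit / sampling_rate_hz,
      provenance = "multiunit"
    )
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$unit, out$time_samples), ]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
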
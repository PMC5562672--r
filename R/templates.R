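#' Template-cluster selection criteria
#'
#' Codifies the manual single-unit screening of the clustering pass: keep the
#' large, well-isolated clusters, drop clusters of small-amplitude waveforms
#' (typical multi-unit activity), drop clusters with many refractory
#' violations (mixtures of cells), require feature stability over the
#' recording, and merge clusters whose mean waveforms are near-identical as
#' long as the merge adds no refractory violations. `include` / `exclude`
#' arguments of [select_template_clusters()] override every criterion, so
#' fully manual curation remains possible.
#'
#' @param min_cluster_size Minimum member count (default 60).
#' @param min_isolation Minimum isolation distance (default 1.5; deliberately
#'   lenient - well-isolated real clusters can score low in some feature
#'   spaces).
#' @param max_isi_violation Maximum fraction of inter-spike intervals under
#'   1 ms (default 0.01).
#' @param min_peak_amp_uV Amplitude floor on the mean waveform's deepest
#'   trough, in microvolts; conventionally 1.5 x the extraction threshold.
#' @param merge_corr Pearson correlation of mean waveforms at or above which
#'   two clusters are merge candidates (default 0.95).
#' @param max_drift Bound on the absolute normalized feature drift (fraction
#'   of the feature SD moved over the recording; default 1.0). A cluster is
#'   rejected only when a feature's trend exceeds the bound and is
#'   statistically significant (Bonferroni-corrected 1% level), so the
#'   sampling noise of modest clusters is not mistaken for electrode drift.
#' @param refractory_ms Refractory period used by the ISI criterion.
#' @return A list of class `template_criteria`.
#' @export
template_criteria <- function(min_cluster_size = 60L,
                              min_isolation = 1.5,
                              max_isi_violation = 0.01,
                              min_peak_amp_uV = 0,
                              merge_corr = 0.95,
                              max_drift = 1.0,
                              refractory_ms = 1.0) {
  stopifnot(max_isi_violation >= 0, max_isi_violation <= 1,
            merge_corr >= -1, merge_corr <= 1)
  structure(
    list(min_cluster_size = as.integer(min_cluster_size),
         min_isolation = min_isolation,
         max_isi_violation = max_isi_violation,
         min_peak_amp_uV = min_peak_amp_uV,
         merge_corr = merge_corr,
         max_drift = max_drift,
         refractory_ms = refractory_ms),
    class = "template_criteria"
  )
}

# A cluster counts as drifting when some feature moves more than max_drift
# SDs over the recording AND the trend is statistically significant; the
# significance guard keeps the sampling noise of small clusters from
# masquerading as drift.
drifting <- function(feats, times, max_drift, alpha = 0.01) {
  if (nrow(feats) < 10L) return(FALSE)
  alpha <- alpha / ncol(feats)  # Bonferroni across features
  for (j in seq_len(ncol(feats))) {
    v <- feats[, j]
    if (stats::sd(v) == 0) next
    if (abs(drift_metric(v, times)) <= max_drift) next
    p <- stats::cor.test(as.numeric(times), v)$p.value
    if (p < alpha) return(TRUE)
  }
  FALSE
}

# mean waveform (channels x window) of a member set
mean_waveform <- function(spikes, idx) {
  d <- dim(spikes$waveforms)
  w <- spikes$waveforms[idx, , , drop = FALSE]
  matrix(apply(w, c(2L, 3L), mean), nrow = d[2L])
}

#' Normalized feature drift over time
#'
#' Least-squares slope of a feature against spike time, multiplied by the
#' spanned duration and divided by the feature's SD: the drift over the whole
#' recording expressed as a fraction of the feature's spread. Values near 0
#' indicate a stable cluster.
#'
#' @param feature_values Numeric vector, one value per spike.
#' @param trigger_times Spike times (samples), at least 10 spikes.
#' @return Unitless normalized slope.
#' @export
drift_metric <- function(feature_values, trigger_times) {
  stopifnot(length(feature_values) == length(trigger_times),
            length(feature_values) >= 10L)
  s <- stats::sd(feature_values)
  if (s == 0) return(0)
  t0 <- as.numeric(trigger_times)
  slope <- stats::cov(t0, feature_values) / stats::var(t0)
  slope * (max(t0) - min(t0)) / s
}

#' Select and merge single-unit template clusters
#'
#' Two-stage screening of the clusters of a [cem_cluster()] model. Stage one
#' removes clusters that may not contribute to any template: mixtures
#' (ISI violation fraction above `max_isi_violation`), multi-unit-like
#' clusters (mean-waveform trough above the amplitude floor), and unstable
#' clusters (normalized feature drift beyond `max_drift`). Surviving clusters
#' are then greedily merged - most-correlated pair first, requiring mean-
#' waveform Pearson r at or above `merge_corr` and a merged ISI fraction that
#' stays within bounds - so a unit split across several clusters is
#' reassembled before judgment. Stage two keeps the merged groups that are
#' large (`min_cluster_size`) and well isolated (`min_isolation`, isolation
#' distance of the group against all remaining spikes).
#'
#' @param spikes The clustered [spike_set()].
#' @param features Feature matrix used for the clustering (isolation distance
#'   and drift are computed in this space).
#' @param model A [cem_cluster()] model over `spikes`.
#' @param criteria A [template_criteria()].
#' @param sampling_rate_hz Sampling rate of the source recording.
#' @param include Cluster ids to force-keep regardless of criteria.
#' @param exclude Cluster ids to drop regardless of criteria.
#' @return List of integer vectors; each element is a group of cluster ids
#'   forming one single unit. Empty (with a warning) when nothing passes.
#' @export
select_template_clusters <- function(spikes, features, model, criteria,
                                     sampling_rate_hz,
                                     include = integer(0),
                                     exclude = integer(0)) {
  labels <- model$labels
  ids <- sort(unique(labels))
  # stage 1 - safety screens: clusters that look like mixtures (refractory
  # violations), multi-unit activity (small amplitudes) or unstable
  # recordings can neither become templates nor be merged into one
  passing <- integer(0)
  for (id in ids) {
    if (id %in% exclude) next
    if (id %in% include) { passing <- c(passing, id); next }
    members <- which(labels == id)
    times <- spikes$trigger_times[members]
    if (isi_violation_fraction(times, sampling_rate_hz,
                               criteria$refractory_ms) >
        criteria$max_isi_violation) next
    mw <- mean_waveform(spikes, members)
    if (max(-apply(mw, 1L, min)) < criteria$min_peak_amp_uV) next
    if (length(members) >= 10L && drifting(features[members, , drop = FALSE],
                                            times, criteria$max_drift)) next
    passing <- c(passing, id)
  }
  if (length(passing) == 0L) {
    warning("no clusters passed the template criteria")
    return(list())
  }
  groups <- as.list(passing)
  forbidden <- character(0)
  pair_key <- function(gi, gj) {
    paste(sort(c(min(gi), min(gj))), collapse = "-")
  }
  repeat {
    if (length(groups) < 2L) break
    mws <- lapply(groups, function(g) {
      as.vector(mean_waveform(spikes, which(labels %in% g)))
    })
    best <- NULL
    for (i in seq_len(length(groups) - 1L)) {
      for (j in (i + 1L):length(groups)) {
        if (pair_key(groups[[i]], groups[[j]]) %in% forbidden) next
        r <- stats::cor(mws[[i]], mws[[j]])
        if (is.finite(r) && r >= criteria$merge_corr &&
            (is.null(best) || r > best$r)) {
          best <- list(i = i, j = j, r = r)
        }
      }
    }
    if (is.null(best)) break
    merged <- c(groups[[best$i]], groups[[best$j]])
    times <- sort(spikes$trigger_times[labels %in% merged])
    if (isi_violation_fraction(times, sampling_rate_hz,
                               criteria$refractory_ms) <=
        criteria$max_isi_violation) {
      groups[[best$i]] <- merged
      groups[[best$j]] <- NULL
      # merged group inherits a new min id; old forbidden keys remain valid
    } else {
      forbidden <- c(forbidden, pair_key(groups[[best$i]], groups[[best$j]]))
    }
  }
  # stage 2 - quality gates on the merged groups: keep the large,
  # well-isolated ones (forced includes bypass the gates)
  keep <- vapply(groups, function(g) {
    if (any(g %in% include)) return(TRUE)
    members <- which(labels %in% g)
    if (length(members) < criteria$min_cluster_size) return(FALSE)
    glab <- ifelse(labels %in% g, 1L, 2L)
    iso <- isolation_distance(features, glab, 1L)
    !(is.finite(iso) && iso < criteria$min_isolation)
  }, logical(1))
  groups <- groups[keep]
  if (length(groups) == 0L) {
    warning("no clusters passed the template criteria")
  }
  groups
}

#' Build single-unit templates
#'
#' Averages the member waveforms of each selected cluster group into a
#' template and attaches quality statistics (isolation distance of the
#' largest source cluster, ISI violation fraction, member count).
#'
#' @inheritParams select_template_clusters
#' @param labels Cluster label per spike (from the model).
#' @param groups Output of [select_template_clusters()].
#' @return List of `template` objects: `unit_id`, `waveform`
#'   (`n_channels x 32` matrix, trough at sample 11), `trigger_index` (11),
#'   `source_clusters`, `member_index`, `quality`.
#' @export
build_templates <- function(spikes, labels, groups, features = NULL,
                            sampling_rate_hz = 30000) {
  if (length(groups) == 0L) stop("no template groups")
  out <- vector("list", length(groups))
  for (u in seq_along(groups)) {
    g <- groups[[u]]
    members <- which(labels %in% g)
    if (length(members) == 0L) stop("empty template group")
    iso <- NA_real_
    if (!is.null(features)) {
      main <- g[which.max(vapply(g, function(id) sum(labels == id), 0))]
      iso <- isolation_distance(features, labels, main)
    }
    times <- spikes$trigger_times[members]
    out[[u]] <- structure(
      list(
        unit_id = u,
        waveform = mean_waveform(spikes, members),
        trigger_index = 11L,
        source_clusters = g,
        member_index = members,
        quality = list(
          isolation = iso,
          isi_fraction = isi_violation_fraction(times, sampling_rate_hz),
          n_members = length(members)
        )
      ),
      class = "template"
    )
  }
  out
}

#' @export
print.template <- function(x, ...) {
  cat(sprintf(
    "<template> unit %d: %d channel(s), trough %.1f uV, %d member spikes\n",
    x$unit_id, nrow(x$waveform), min(x$waveform), x$quality$n_members
  ))
  invisible(x)
}
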
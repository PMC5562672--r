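#' Jointly re-cluster non-template spikes with the synthetic bank
#'
#' Pools the recorded spikes that did not belong to any template cluster with
#' the synthetic waveforms (each synthetic entering exactly once), computes
#' the requested features on the union - so normalization and the principal
#' component axis are shared between real and synthetic waveforms - and
#' clusters the union with the CEM engine. Overlapping waveforms are expected
#' to land in the same clusters as the synthetics they resemble.
#'
#' @param nontemplate_spikes A [spike_set()] of the non-template spikes.
#' @param bank A [generate_bank()] result.
#' @param spec A [feature_spec()] for the joint pass.
#' @param cfg A [cluster_config()].
#' @return List: `labels` (joint cluster id per union item, reals first),
#'   `is_synthetic` (flag per union item), `synthetic_id` (bank id or `NA`),
#'   `features` (the joint z-scored feature matrix), `model`.
#' @export
recluster_with_bank <- function(nontemplate_spikes, bank, spec, cfg) {
  n_real <- n_spikes(nontemplate_spikes)
  n_syn <- nrow(bank$meta)
  if (n_syn == 0L) stop("empty synthetic bank")
  if (n_real == 0L) {
    return(list(labels = integer(0), is_synthetic = logical(0),
                synthetic_id = integer(0), features = NULL, model = NULL))
  }
  d <- dim(nontemplate_spikes$waveforms)
  union_w <- array(0, dim = c(n_real + n_syn, d[2L], d[3L]))
  union_w[seq_len(n_real), , ] <- nontemplate_spikes$waveforms
  union_w[n_real + seq_len(n_syn), , ] <- bank$waveforms
  union_spikes <- structure(
    list(waveforms = union_w,
         trigger_times = seq_len(n_real + n_syn),  # placeholder ordering
         trigger_channels = c(nontemplate_spikes$trigger_channels,
                              bank$meta$trigger_channel),
         source_id = "joint"),
    class = "spike_set"
  )
  feats <- normalize_features(compute_features(union_spikes, spec))
  if (nrow(feats) <= cfg$max_K) {
    cfg$max_K <- max(cfg$min_K, min(cfg$max_K, nrow(feats) - 1L))
  }
  model <- cem_cluster(feats, cfg)
  list(
    labels = model$labels,
    is_synthetic = c(rep(FALSE, n_real), rep(TRUE, n_syn)),
    synthetic_id = c(rep(NA_integer_, n_real), bank$meta$id),
    features = feats,
    model = model
  )
}

#' Best-matching synthetic waveform per spike
#'
#' Within every joint cluster containing both real and synthetic waveforms,
#' computes the Pearson correlation between each real spike's concatenated
#' channel samples and each co-clustered synthetic's, and selects the
#' synthetic with the highest correlation (ties broken toward the lowest
#' synthetic id). Real spikes in clusters without synthetics receive no match
#' and fall to the multi-unit pool. No minimum correlation is imposed: the
#' joint clustering, not a similarity threshold, decides which waveforms are
#' comparable.
#'
#' @param joint Output of [recluster_with_bank()].
#' @param spikes The non-template [spike_set()] (same order as the reals in
#'   `joint`).
#' @param bank The [generate_bank()] result.
#' @return Data frame with one row per real spike: `spike_index`,
#'   `synthetic_id` (`NA` when unmatched), `pearson_r`, `cluster_id`.
#' @export
best_match <- function(joint, spikes, bank) {
  n_real <- sum(!joint$is_synthetic)
  out <- data.frame(
    spike_index = seq_len(n_real),
    synthetic_id = rep(NA_integer_, n_real),
    pearson_r = rep(NA_real_, n_real),
    cluster_id = joint$labels[seq_len(n_real)]
  )
  if (n_real == 0L) return(out)
  real_flat <- flatten_waveforms(spikes$waveforms)
  syn_flat <- flatten_waveforms(bank$waveforms)
  syn_ids <- bank$meta$id
  zero_var_warned <- FALSE
  for (cl in sort(unique(joint$labels))) {
    in_cl <- joint$labels == cl
    syn_here <- which(in_cl & joint$is_synthetic)
    real_here <- which(in_cl & !joint$is_synthetic)
    if (length(syn_here) == 0L || length(real_here) == 0L) next
    sid <- joint$synthetic_id[syn_here]
    srows <- match(sid, syn_ids)
    S <- t(syn_flat[srows, , drop = FALSE])
    R <- t(real_flat[real_here, , drop = FALSE])
    svar <- apply(S, 2L, stats::var) > 0
    rvar <- apply(R, 2L, stats::var) > 0
    cc <- matrix(0, length(real_here), length(syn_here))
    if (any(rvar) && any(svar)) {
      cc[rvar, svar] <- stats::cor(R[, rvar, drop = FALSE],
                                   S[, svar, drop = FALSE])
    }
    if ((!all(rvar) || !all(svar)) && !zero_var_warned) {
      warning("zero-variance waveform in correlation matching; r set to 0")
      zero_var_warned <- TRUE
    }
    # argmax r per real spike; ties toward the lowest synthetic id
    ord <- order(sid)
    for (i in seq_along(real_here)) {
      ri <- cc[i, ord]
      k <- ord[which.max(ri)]
      out$synthetic_id[real_here[i]] <- sid[k]
      out$pearson_r[real_here[i]] <- cc[i, k]
    }
  }
  out
}

#' Spikes forming the multi-unit pool
#'
#' All non-template spikes whose joint cluster contained no synthetic
#' waveform; together with the matched spikes they partition the non-template
#' set.
#'
#' @param results A [best_match()] data frame.
#' @return Integer vector of spike indices.
#' @export
collect_multiunit <- function(results) {
  results$spike_index[is.na(results$synthetic_id)]
}
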
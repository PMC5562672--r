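#' Waveform feature specification
#'
#' Defines which shape descriptors are computed per spike. Available features
#' (applied per channel unless noted): `area` = sum of absolute voltages
#' (absolute so biphasic waveforms do not cancel); `trigger_value` = voltage
#' at the trigger sample (local sample 11); `peak` = maximum voltage;
#' `width` = sample index of the maximum minus sample index of the minimum;
#' `energy` = sum of squared voltages; `fft` = magnitudes of the first
#' `fft_bins` non-DC discrete Fourier bins; `pc1` = projection onto the first
#' principal component of the mean-centered waveform set, computed once on the
#' concatenated channels; `wavelet` = Haar wavelet coefficients selected by
#' multimodality (see [wavelet_features()]).
#'
#' @param feature_names Ordered character vector drawn from the set above.
#' @param per_channel Compute channelwise features on every channel and
#'   concatenate (`TRUE`, the tetrode convention) or on the trigger channel's
#'   block only.
#' @param fft_bins Number of low-frequency DFT magnitude bins (default 3).
#' @param wavelet_m Number of dip-ranked wavelet coefficients kept (default 4).
#' @param wavelet_coeffs Optional explicit coefficient indices overriding the
#'   multimodality ranking.
#' @return A list of class `feature_spec`.
#' @export
feature_spec <- function(feature_names, per_channel = TRUE, fft_bins = 3L,
                         wavelet_m = 4L, wavelet_coeffs = NULL) {
  known <- c("area", "trigger_value", "fft", "pc1", "peak", "width",
             "energy", "wavelet")
  if (length(feature_names) == 0L) stop("feature_names must be non-empty")
  bad <- setdiff(feature_names, known)
  if (length(bad)) stop("unknown features: ", paste(bad, collapse = ", "))
  stopifnot(fft_bins >= 1L)
  structure(
    list(feature_names = feature_names, per_channel = per_channel,
         fft_bins = as.integer(fft_bins), wavelet_m = as.integer(wavelet_m),
         wavelet_coeffs = wavelet_coeffs),
    class = "feature_spec"
  )
}

#' Named feature presets
#'
#' `electrode_features()` is the single-electrode re-clustering set (area,
#' trigger value, FFT, first principal component); `tetrode_features()` adds
#' spike width and peak value.
#'
#' @param fft_bins Number of FFT magnitude bins (default 3).
#' @return A [feature_spec()].
#' @export
electrode_features <- function(fft_bins = 3L) {
  feature_spec(c("area", "trigger_value", "fft", "pc1"), fft_bins = fft_bins)
}

#' @rdname electrode_features
#' @export
tetrode_features <- function(fft_bins = 3L) {
  feature_spec(c("area", "trigger_value", "fft", "pc1", "width", "peak"),
               fft_bins = fft_bins)
}

# channelwise feature block for an n x L matrix of single-channel waveforms
channel_features <- function(m, spec, trigger_index = 11L) {
  out <- list()
  for (f in spec$feature_names) {
    block <- switch(
      f,
      area = matrix(rowSums(abs(m)), ncol = 1L,
                    dimnames = list(NULL, "area")),
      trigger_value = matrix(m[, trigger_index], ncol = 1L,
                             dimnames = list(NULL, "trigger_value")),
      peak = matrix(apply(m, 1L, max), ncol = 1L,
                    dimnames = list(NULL, "peak")),
      width = matrix(apply(m, 1L, which.max) - apply(m, 1L, which.min),
                     ncol = 1L, dimnames = list(NULL, "width")),
      energy = matrix(rowSums(m^2), ncol = 1L,
                      dimnames = list(NULL, "energy")),
      fft = {
        mag <- Mod(stats::mvfft(t(m)))[2:(1L + spec$fft_bins), , drop = FALSE]
        b <- t(mag)
        colnames(b) <- paste0("fft", seq_len(spec$fft_bins))
        b
      },
      NULL # pc1 / wavelet handled on the concatenated waveform
    )
    if (!is.null(block)) out[[f]] <- block
  }
  if (length(out) == 0L) return(NULL)
  do.call(cbind, out)
}

#' Compute waveform features
#'
#' One row per spike. Channelwise features are computed per channel and
#' concatenated when `spec$per_channel` is `TRUE`; `pc1` is always a single
#' column computed on the concatenated multi-channel waveform.
#'
#' @param spikes A [spike_set()].
#' @param spec A [feature_spec()].
#' @return Numeric matrix `n_spikes x n_features` with named columns.
#' @export
compute_features <- function(spikes, spec) {
  n <- n_spikes(spikes)
  if (n == 0L) stop("empty spike set")
  d <- dim(spikes$waveforms)
  blocks <- list()
  chan_names <- setdiff(spec$feature_names, c("pc1", "wavelet"))
  if (length(chan_names)) {
    chan_spec <- spec
    chan_spec$feature_names <- chan_names
    channels <- if (spec$per_channel) seq_len(d[2L]) else 1L
    for (ch in channels) {
      b <- channel_features(spikes$waveforms[, ch, , drop = TRUE] |>
                              matrix(nrow = n), chan_spec)
      if (d[2L] > 1L && spec$per_channel) {
        colnames(b) <- paste0("ch", ch, "_", colnames(b))
      }
      blocks[[length(blocks) + 1L]] <- b
    }
  }
  if ("pc1" %in% spec$feature_names) {
    if (n < 2L) stop("pc1 requires at least 2 spikes")
    flat <- flatten_waveforms(spikes$waveforms)
    ctr <- scale(flat, center = TRUE, scale = FALSE)
    sv <- svd(ctr, nu = 0L, nv = 1L)
    b <- matrix(ctr %*% sv$v[, 1L], ncol = 1L, dimnames = list(NULL, "pc1"))
    blocks[[length(blocks) + 1L]] <- b
  }
  if ("wavelet" %in% spec$feature_names) {
    b <- wavelet_features(spikes, spec)$selected
    blocks[[length(blocks) + 1L]] <- b
  }
  out <- do.call(cbind, blocks)
  if (any(!is.finite(out))) stop("non-finite feature values")
  out
}

#' Z-score feature columns
#'
#' Centers and scales every column; constant columns are left centered with
#' unit divisor. The centering and scaling vectors are attached as attributes
#' so the normalization is exactly reproducible (and can be re-applied to new
#' rows).
#'
#' @param features Numeric feature matrix.
#' @return Scaled matrix with attributes `center` and `scale`.
#' @export
normalize_features <- function(features) {
  ctr <- colMeans(features)
  scl <- apply(features, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  out <- sweep(sweep(features, 2L, ctr), 2L, scl, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}
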
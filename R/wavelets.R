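#' Haar discrete wavelet transform
#'
#' Full orthonormal Haar decomposition of a dyadic-length signal: the
#' coefficient vector holds the final approximation coefficient first, then
#' detail coefficients from the coarsest to the finest level. For a 32-sample
#' waveform this yields exactly 32 coefficients and preserves energy.
#'
#' @param x Numeric vector whose length is a power of two.
#' @return Numeric coefficient vector of the same length.
#' @export
haar_dwt <- function(x) {
  n <- length(x)
  if (n < 2L || bitwAnd(n, n - 1L) != 0L) {
    stop("haar_dwt requires a power-of-two length")
  }
  details <- list()
  a <- x
  while (length(a) > 1L) {
    odd <- a[seq(1L, length(a), 2L)]
    even <- a[seq(2L, length(a), 2L)]
    details[[length(details) + 1L]] <- (odd - even) / sqrt(2)
    a <- (odd + even) / sqrt(2)
  }
  c(a, unlist(rev(details)))
}

#' Hartigan dip statistic (envelope decomposition)
#'
#' Departure-from-unimodality score: for every candidate mode location the
#' empirical cdf is approximated by a convex function to the left (greatest
#' convex minorant) and a concave function to the right (least concave
#' majorant); the best achievable sup-norm error is half the larger envelope
#' gap, and the dip is the minimum of that error over mode locations. Larger
#' values indicate stronger multimodality; the statistic is invariant to
#' shifting and positive scaling of the sample. Samples larger than
#' `max_points` are reduced to evenly spaced order statistics, keeping the
#' computation quadratic in at most `max_points`.
#'
#' @param x Numeric sample (at least 3 finite values).
#' @param max_points Order-statistic cap (default 1000).
#' @return The dip value, a number in (0, 0.25].
#' @export
dip_statistic <- function(x, max_points = 1000L) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 3L) stop("dip_statistic needs at least 3 values")
  Fx <- (seq_len(n) - 0.5) / n
  if (n > max_points) {
    keep <- unique(round(seq(1L, n, length.out = max_points)))
    x <- x[keep]; Fx <- Fx[keep]
  }
  # collapse tied values to their mid cdf height
  if (anyDuplicated(x)) {
    Fx <- tapply(Fx, match(x, unique(x)), mean)
    x <- unique(x)
    names(Fx) <- NULL
  }
  k <- length(x)
  if (k < 3L) return(0.5 / n)
  e_conv <- envelope_gaps(x, Fx, lower = TRUE)
  e_conc <- rev(envelope_gaps(rev(-x), rev(-Fx) - min(-Fx), lower = TRUE))
  0.5 * min(pmax(e_conv, e_conc))
}

# e[m] = max gap between the points (x_i, F_i), i <= m, and the lower convex
# hull of those points. Reversing and negating turns the concave-majorant
# suffix computation into the same primitive.
envelope_gaps <- function(x, Fx, lower = TRUE) {
  k <- length(x)
  e <- numeric(k)
  hull <- c(1L)
  for (m in 2:k) {
    while (length(hull) >= 2L) {
      p <- hull[length(hull) - 1L]; q <- hull[length(hull)]
      # pop q unless it lies strictly below segment p-m
      if ((Fx[q] - Fx[p]) * (x[m] - x[q]) >= (Fx[m] - Fx[q]) * (x[q] - x[p])) {
        hull <- hull[-length(hull)]
      } else break
    }
    hull <- c(hull, m)
    g <- stats::approx(x[hull], Fx[hull], xout = x[1:m], ties = "ordered")$y
    e[m] <- max(Fx[1:m] - g)
  }
  e
}

#' Wavelet coefficients with multimodality ranking
#'
#' Computes the full Haar decomposition of every waveform (per channel,
#' concatenated), scores each coefficient's across-spike distribution with the
#' dip statistic, and selects the `spec$wavelet_m` most multimodal
#' coefficients as clustering features. Multimodal coefficient distributions
#' are the ones that separate units, so ranking by the dip automates the
#' usual manual coefficient picking; an explicit `spec$wavelet_coeffs` list
#' overrides the ranking.
#'
#' @param spikes A [spike_set()].
#' @param spec A [feature_spec()] (fields `wavelet_m`, `wavelet_coeffs`).
#' @return List with `coefficients` (n_spikes x n_coeff matrix), `dip`
#'   (score per coefficient), `ranking` (coefficient indices, most multimodal
#'   first) and `selected` (the chosen columns).
#' @export
wavelet_features <- function(spikes, spec = feature_spec("wavelet")) {
  n <- n_spikes(spikes)
  d <- dim(spikes$waveforms)
  coef <- NULL
  for (ch in seq_len(d[2L])) {
    m <- matrix(spikes$waveforms[, ch, , drop = TRUE], nrow = n)
    cc <- t(apply(m, 1L, haar_dwt))
    colnames(cc) <- paste0(if (d[2L] > 1L) paste0("ch", ch, "_") else "",
                           "w", seq_len(ncol(cc)))
    coef <- cbind(coef, cc)
  }
  dip <- if (n >= 3L) apply(coef, 2L, dip_statistic) else rep(NA_real_, ncol(coef))
  ranking <- order(dip, decreasing = TRUE)
  sel_idx <- if (!is.null(spec$wavelet_coeffs)) {
    spec$wavelet_coeffs
  } else {
    ranking[seq_len(min(spec$wavelet_m, ncol(coef)))]
  }
  list(coefficients = coef, dip = dip, ranking = ranking,
       selected = coef[, sel_idx, drop = FALSE])
}
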
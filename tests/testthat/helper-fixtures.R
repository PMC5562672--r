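# Shared fixtures, all generated in code.

# A single negative Gaussian pulse of given depth centred at `at` (samples).
gaussian_pulse_trace <- function(n, at, depth, sd_samples = 2,
                                 noise_sd = 0, seed = 1) {
  set.seed(seed)
  t <- seq_len(n)
  x <- -depth * exp(-(t - at)^2 / (2 * sd_samples^2))
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  x
}

# Small deterministic spike set: `n` copies of a template with additive noise.
noisy_spike_set <- function(n, template = overlapsort:::electrode_sim_templates()[[1]],
                            noise_sd = 0, seed = 1, spacing = 100L) {
  set.seed(seed)
  nch <- nrow(template$waveform)
  w <- array(0, dim = c(n, nch, 32))
  for (i in seq_len(n)) {
    w[i, , ] <- template$waveform + matrix(rnorm(nch * 32, 0, noise_sd), nch)
  }
  spike_set(w, trigger_times = seq_len(n) * spacing)
}

# Two well-separated Gaussian blobs in d dimensions.
two_blob_features <- function(n_per = 200, d = 2, sep = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * d), ncol = d),
             matrix(rnorm(n_per * d, mean = sep), ncol = d))
  list(x = x, truth = rep(1:2, each = n_per))
}

expect_label_agreement <- function(labels, truth, min_agree) {
  tab <- table(labels, truth)
  # best one-to-one relabelling on a 2x2-ish table: greedy works here
  agree <- 0
  while (length(tab) && nrow(tab) && ncol(tab)) {
    best <- arrayInd(which.max(tab), dim(tab))
    agree <- agree + tab[best[1], best[2]]
    tab <- tab[-best[1], -best[2], drop = FALSE]
  }
  expect_gte(agree / length(truth), min_agree)
}
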
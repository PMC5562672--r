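make_joint_fixture <- function(noise_sd = 3, n_real = 40, seed = 50) {
  set.seed(seed)
  tpl <- overlapsort:::electrode_sim_templates()
  bank <- generate_bank(tpl, threshold_uV = 40)
  syn_flat <- overlapsort:::flatten_waveforms(bank$waveforms)
  pick <- sample.int(nrow(bank$meta), n_real, replace = TRUE)
  w <- array(0, dim = c(n_real, 1, 32))
  for (i in seq_len(n_real)) {
    w[i, 1, ] <- syn_flat[pick[i], ] + rnorm(32, 0, noise_sd)
  }
  spikes <- spike_set(w, trigger_times = seq_len(n_real) * 1000L)
  list(tpl = tpl, bank = bank, spikes = spikes, pick = pick)
}

test_that("the joint union holds each synthetic exactly once and partitions", {
  fx <- make_joint_fixture()
  joint <- suppressWarnings(recluster_with_bank(
    fx$spikes, fx$bank, electrode_features(),
    cluster_config(min_K = 4, max_K = 10, restarts = 2, seed = 2)))
  n_union <- length(joint$labels)
  expect_identical(n_union, n_spikes(fx$spikes) + nrow(fx$bank$meta))
  expect_identical(sum(joint$is_synthetic), nrow(fx$bank$meta))
  expect_setequal(joint$synthetic_id[joint$is_synthetic], fx$bank$meta$id)
  expect_true(all(joint$labels >= 1))
})

test_that("an empty non-template set resolves to an empty result", {
  fx <- make_joint_fixture(n_real = 1)
  empty <- subset_spikes(fx$spikes, integer(0))
  got <- recluster_with_bank(empty, fx$bank, electrode_features(),
                             cluster_config())
  expect_length(got$labels, 0L)
})

test_that("best_match returns the argmax-correlation synthetic in-cluster", {
  fx <- make_joint_fixture(noise_sd = 0.5, n_real = 12, seed = 51)
  n_syn <- nrow(fx$bank$meta)
  # construct a single joint cluster holding everything: the argmax is then
  # checked against a brute-force correlation over the whole bank
  joint <- list(
    labels = rep(1L, n_spikes(fx$spikes) + n_syn),
    is_synthetic = c(rep(FALSE, n_spikes(fx$spikes)), rep(TRUE, n_syn)),
    synthetic_id = c(rep(NA_integer_, n_spikes(fx$spikes)), fx$bank$meta$id)
  )
  mm <- best_match(joint, fx$spikes, fx$bank)
  syn_flat <- overlapsort:::flatten_waveforms(fx$bank$waveforms)
  real_flat <- overlapsort:::flatten_waveforms(fx$spikes$waveforms)
  for (i in seq_len(nrow(mm))) {
    rr <- as.vector(cor(real_flat[i, ], t(syn_flat)))
    expect_identical(mm$synthetic_id[i], which.max(rr))
    expect_equal(mm$pearson_r[i], max(rr))
  }
})

test_that("a spike identical to a synthetic matches it with r = 1", {
  fx <- make_joint_fixture(noise_sd = 0, n_real = 5, seed = 52)
  n_syn <- nrow(fx$bank$meta)
  joint <- list(
    labels = rep(1L, 5L + n_syn),
    is_synthetic = c(rep(FALSE, 5L), rep(TRUE, n_syn)),
    synthetic_id = c(rep(NA_integer_, 5L), fx$bank$meta$id)
  )
  mm <- best_match(joint, fx$spikes, fx$bank)
  expect_equal(mm$pearson_r, rep(1, 5), tolerance = 1e-12)
  expect_identical(mm$synthetic_id, fx$pick)
})

test_that("correlation matching is scale- and offset-invariant", {
  fx <- make_joint_fixture(noise_sd = 2, n_real = 8, seed = 53)
  n_syn <- nrow(fx$bank$meta)
  joint <- list(
    labels = rep(1L, 8L + n_syn),
    is_synthetic = c(rep(FALSE, 8L), rep(TRUE, n_syn)),
    synthetic_id = c(rep(NA_integer_, 8L), fx$bank$meta$id)
  )
  m1 <- best_match(joint, fx$spikes, fx$bank)
  scaled <- fx$spikes
  scaled$waveforms <- 2.7 * fx$spikes$waveforms + 13
  m2 <- best_match(joint, scaled, fx$bank)
  expect_identical(m1$synthetic_id, m2$synthetic_id)
})

test_that("spikes in synthetic-free clusters form the multi-unit pool", {
  fx <- make_joint_fixture(n_real = 6, seed = 54)
  n_syn <- nrow(fx$bank$meta)
  labels <- c(rep(2L, 6L), rep(1L, n_syn))  # reals isolated in cluster 2
  joint <- list(labels = labels,
                is_synthetic = c(rep(FALSE, 6L), rep(TRUE, n_syn)),
                synthetic_id = c(rep(NA_integer_, 6L), fx$bank$meta$id))
  mm <- best_match(joint, fx$spikes, fx$bank)
  expect_true(all(is.na(mm$synthetic_id)))
  expect_identical(collect_multiunit(mm), 1:6)

  # conservation: matched and multi-unit partition the non-template spikes
  labels[1:3] <- 1L
  joint$labels <- labels
  mm2 <- best_match(joint, fx$spikes, fx$bank)
  matched <- mm2$spike_index[!is.na(mm2$synthetic_id)]
  expect_setequal(c(matched, collect_multiunit(mm2)), 1:6)
  expect_length(intersect(matched, collect_multiunit(mm2)), 0L)
})

test_that("a zero-variance waveform matches with r = 0 and a warning", {
  fx <- make_joint_fixture(n_real = 2, seed = 55)
  fx$spikes$waveforms[1, 1, ] <- 5  # flat line
  n_syn <- nrow(fx$bank$meta)
  joint <- list(labels = rep(1L, 2L + n_syn),
                is_synthetic = c(rep(FALSE, 2L), rep(TRUE, n_syn)),
                synthetic_id = c(rep(NA_integer_, 2L), fx$bank$meta$id))
  expect_warning(mm <- best_match(joint, fx$spikes, fx$bank), "zero-variance")
  expect_equal(mm$pearson_r[1], 0)
  expect_identical(mm$synthetic_id[1], 1L)  # tie broken to lowest id
})

test_that("noisy copies of generating pairs recover the correct parent pair
           at trough-SNR 8", {
  set.seed(56)
  tpl <- overlapsort:::electrode_sim_templates()
  bank <- generate_bank(tpl, threshold_uV = 40)
  snr <- 8
  n_real <- 90
  syn_flat <- overlapsort:::flatten_waveforms(bank$waveforms)
  pick <- sample.int(nrow(bank$meta), n_real, replace = TRUE)
  w <- array(0, dim = c(n_real, 1, 32))
  for (i in seq_len(n_real)) {
    sg <- max(-syn_flat[pick[i], ]) / snr   # per-waveform trough SNR
    w[i, 1, ] <- syn_flat[pick[i], ] + rnorm(32, 0, sg)
  }
  spikes <- spike_set(w, trigger_times = seq_len(n_real) * 1000L)
  joint <- suppressWarnings(recluster_with_bank(
    spikes, bank, electrode_features(),
    cluster_config(min_K = 6, max_K = 16, K_step = 2, restarts = 3,
                   seed = 9)))
  mm <- best_match(joint, spikes, bank)
  pair_key <- function(rows) paste(pmin(bank$meta$unit_a[rows],
                                        bank$meta$unit_b[rows]),
                                   pmax(bank$meta$unit_a[rows],
                                        bank$meta$unit_b[rows]))
  ok <- !is.na(mm$synthetic_id)
  correct <- ok
  correct[ok] <- pair_key(match(mm$synthetic_id[ok], bank$meta$id)) ==
    pair_key(pick[ok])
  expect_gte(mean(correct), 0.9)
})
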
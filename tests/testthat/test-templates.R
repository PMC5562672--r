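test_that("templates are member means and order-invariant", {
  tpl <- overlapsort:::electrode_sim_templates()[[1]]
  spikes <- noisy_spike_set(8, template = tpl, noise_sd = 0)
  got <- build_templates(spikes, rep(1L, 8), list(1L))
  expect_equal(got[[1]]$waveform, tpl$waveform)

  w <- array(0, dim = c(2, 1, 32))
  w[1, , ] <- tpl$waveform
  w[2, , ] <- 3 * tpl$waveform
  pair <- spike_set(w, c(10L, 50L))
  got2 <- build_templates(pair, c(1L, 1L), list(1L))
  expect_equal(got2[[1]]$waveform, 2 * tpl$waveform)

  # order of members does not matter
  spikes2 <- noisy_spike_set(20, template = tpl, noise_sd = 6, seed = 81)
  t_a <- build_templates(spikes2, rep(1L, 20), list(1L))[[1]]$waveform
  perm <- subset_spikes(spikes2, c(11:20, 1:10))
  perm$trigger_times <- sort(perm$trigger_times)
  t_b <- build_templates(perm, rep(1L, 20), list(1L))[[1]]$waveform
  expect_equal(t_a, t_b)
  expect_error(build_templates(spikes2, rep(1L, 20), list(integer(0))),
               "empty")
})

test_that("template estimates converge at the law-of-large-numbers rate", {
  tpl <- overlapsort:::electrode_sim_templates()[[1]]
  sigma <- 10
  for (n in c(25, 100)) {
    spikes <- noisy_spike_set(n, template = tpl, noise_sd = sigma, seed = 82)
    est <- build_templates(spikes, rep(1L, n), list(1L))[[1]]$waveform
    rms <- sqrt(mean((est - tpl$waveform)^2))
    expect_lt(rms, 3 * sigma / sqrt(n))
  }
})

test_that("the drift metric has a closed form on a linear trend", {
  set.seed(83)
  t0 <- sort(sample.int(1e6, 500))
  a <- 2e-6
  v <- a * t0
  got <- drift_metric(v, t0)
  expect_equal(got, a * (max(t0) - min(t0)) / sd(v))
  expect_equal(drift_metric(rep(4, 100), seq_len(100)), 0)
})

test_that("white-noise features rarely register as drift", {
  set.seed(84)
  vals <- replicate(200, abs(drift_metric(rnorm(1000), seq_len(1000))))
  expect_gte(mean(vals < 0.2), 0.95)
})

test_that("selection applies amplitude floor, ISI and merge rules", {
  tplA <- overlapsort:::electrode_sim_templates()[[1]]
  tplB <- overlapsort:::electrode_sim_templates()[[2]]
  set.seed(85)
  n_per <- 80
  mk <- function(tpl, scale, t_start) {
    s <- noisy_spike_set(n_per, template = tpl, noise_sd = 3,
                         seed = t_start)
    s$waveforms <- s$waveforms * scale
    s$trigger_times <- s$trigger_times + t_start
    s
  }
  sA1 <- mk(tplA, 1, 0L); sA2 <- mk(tplA, 1.05, 40L)
  sB <- mk(tplB, 1, 55L); sSmall <- mk(tplA, 0.2, 23L)
  w <- abind_spikes <- array(0, dim = c(4 * n_per, 1, 32))
  times <- c(sA1$trigger_times, sA2$trigger_times, sB$trigger_times,
             sSmall$trigger_times)
  o <- order(times)
  all_w <- array(0, dim = c(4 * n_per, 1, 32))
  all_w[1:n_per, , ] <- sA1$waveforms
  all_w[(n_per + 1):(2 * n_per), , ] <- sA2$waveforms
  all_w[(2 * n_per + 1):(3 * n_per), , ] <- sB$waveforms
  all_w[(3 * n_per + 1):(4 * n_per), , ] <- sSmall$waveforms
  labels <- rep(1:4, each = n_per)[o]
  spikes <- spike_set(all_w[o, , , drop = FALSE], times[o])
  feats <- normalize_features(compute_features(spikes, electrode_features()))
  model <- list(labels = labels)
  crit <- template_criteria(min_cluster_size = 50,
                            min_peak_amp_uV = 50, min_isolation = 0)
  groups <- select_template_clusters(spikes, feats, model, crit, 30000)
  key <- sort(vapply(groups, function(g) paste(sort(g), collapse = "+"), ""))
  # the two near-identical full-amplitude copies of unit A merge; the
  # 0.2-scale cluster fails the 50-uV floor
  expect_identical(key, c("1+2", "3"))

  # an exclude list overrides everything; the lone survivor fails the
  # amplitude floor, so nothing remains
  expect_warning(
    g2 <- select_template_clusters(spikes, feats, model, crit, 30000,
                                   exclude = c(1L, 2L, 3L)),
    "no clusters")
  expect_length(g2, 0L)
})

test_that("a cluster pair whose merge would add refractory violations stays
           separate", {
  tplA <- overlapsort:::electrode_sim_templates()[[1]]
  n_per <- 60
  s1 <- noisy_spike_set(n_per, template = tplA, noise_sd = 2, seed = 86)
  # second cluster fires 5 samples after every first-cluster spike
  w <- array(0, dim = c(2 * n_per, 1, 32))
  w[seq(1, 2 * n_per, 2), , ] <- s1$waveforms
  w[seq(2, 2 * n_per, 2), , ] <- s1$waveforms
  times <- as.vector(rbind(s1$trigger_times, s1$trigger_times + 5L))
  spikes <- spike_set(w, times)
  labels <- rep(c(1L, 2L), n_per)
  feats <- normalize_features(compute_features(spikes, electrode_features()))
  crit <- template_criteria(min_cluster_size = 10, min_peak_amp_uV = 0,
                            min_isolation = 0)
  groups <- select_template_clusters(spikes, feats, list(labels = labels),
                                     crit, 30000)
  expect_identical(sort(vapply(groups, paste, collapse = "+", "")),
                   c("1", "2"))
})

test_that("relaxing every criterion never removes a selected group", {
  set.seed(87)
  sim <- simulate_recording(sim_config("electrode", duration_s = 20,
                                       noise_n_trains = 100L, seed = 3))
  filt <- highpass(sim$recording, 300)
  spikes <- detect_spikes(filt, detection_config())
  feats <- normalize_features(compute_features(spikes, electrode_features()))
  model <- suppressWarnings(
    cem_cluster(feats, cluster_config(min_K = 4, max_K = 8, restarts = 2,
                                      seed = 2)))
  strict <- template_criteria(min_cluster_size = 80, min_isolation = 3,
                              min_peak_amp_uV = 60)
  loose <- template_criteria(min_cluster_size = 10, min_isolation = 0,
                             min_peak_amp_uV = 20)
  g_strict <- suppressWarnings(select_template_clusters(
    spikes, feats, model, strict, 30000))
  g_loose <- suppressWarnings(select_template_clusters(
    spikes, feats, model, loose, 30000))
  expect_true(all(unlist(g_strict) %in% unlist(g_loose)))
})
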
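test_that("surrogate trains respect the hard refractory floor", {
  cfg <- sim_config("electrode", duration_s = 1)
  set.seed(70)
  # high-rate stress: candidates arrive far faster than recovery allows
  total <- 0L
  min_isi <- Inf
  while (total < 1e6) {
    tr <- surrogate_train(100, cfg, rate_hz = 400)
    total <- total + length(tr)
    if (length(tr) > 1) min_isi <- min(min_isi, min(diff(tr)))
  }
  expect_gte(min_isi, 0.001)
})

test_that("a zero rate range produces an empty train", {
  cfg <- sim_config("electrode", free_rate_range = c(0, 0))
  set.seed(71)
  expect_length(surrogate_train(10, cfg), 0L)
})

test_that("the realized rate matches a discrete-time Bernoulli oracle", {
  cfg <- sim_config("electrode")
  set.seed(72)
  n_rep <- 30
  got <- vapply(seq_len(n_rep), function(i) {
    length(surrogate_train(600, cfg, rate_hz = 10)) / 600
  }, 0)
  # oracle: per-ms Bernoulli candidates thinned by the same recovery rule
  oracle <- function() {
    dt <- 1e-3
    p <- 10 * dt
    last <- -Inf
    n <- 0L
    for (t in seq(0, 600, by = dt)) {
      if (runif(1) < p) {
        gap <- t - last
        w <- if (gap < 1e-3) 0 else 1 / (1 + exp(-(gap - 2e-3) / 1e-3))
        if (runif(1) < w) { n <- n + 1L; last <- t }
      }
    }
    n / 600
  }
  ref <- vapply(1:10, function(i) oracle(), 0)
  se <- sqrt(var(got) / n_rep + var(ref) / 10)
  expect_lt(abs(mean(got) - mean(ref)), 3 * se + 0.05)
})

test_that("rendering places the template trough exactly at the spike time", {
  tpl <- overlapsort:::electrode_sim_templates()
  out <- render_signal(list(0.05, numeric(0)), tpl, 0.1, 30000)
  t0 <- 0.05 * 30000
  expect_equal(out$recording$samples[1, (t0 - 10):(t0 + 21)],
               tpl[[1]]$waveform[1, ])
  expect_equal(sum(out$recording$samples[1, -((t0 - 10):(t0 + 21))]), 0)

  # two units at the same time add linearly, matching the superposition
  both <- render_signal(list(0.05, 0.05), tpl, 0.1, 30000)
  sp <- superpose(tpl[[1]], tpl[[2]], 0)
  expect_equal(both$recording$samples[1, (t0 - 10):(t0 + 21)],
               sp$waveform[1, ])
})

test_that("edge spikes are skipped with a warning", {
  tpl <- overlapsort:::electrode_sim_templates()
  expect_warning(out <- render_signal(list(c(0.0001, 0.05)), tpl[1], 0.1,
                                      30000), "edge")
  expect_length(out$unit_times[[1]], 1L)
})

test_that("noise construction is exact: max 1 uV pre-scale, zero mean,
           target SD after scaling", {
  cfg <- sim_config("electrode", duration_s = 4, noise_n_trains = 120L,
                    target_noise_sd_uV = 7)
  set.seed(73)
  noise <- make_noise(cfg)
  expect_equal(max(abs(noise$normalized)), 1)
  expect_lt(abs(mean(noise$trace)), 1e-9)
  expect_equal(sd(as.vector(noise$trace)), 7, tolerance = 1e-6)
})

test_that("simulation is bit-reproducible from its seed", {
  cfg <- sim_config("electrode", duration_s = 2, noise_n_trains = 60L,
                    seed = 99)
  s1 <- simulate_recording(cfg)
  s2 <- simulate_recording(cfg)
  expect_identical(s1$recording$samples, s2$recording$samples)
  expect_identical(s1$truth, s2$truth)
})

test_that("overlap flags are symmetric and use a strict 1-ms window", {
  flags <- overlapsort:::overlap_flags(
    list(c(1000L, 5000L), c(1029L, 5030L)), 30000)
  expect_identical(flags[[1]], c(TRUE, FALSE))   # 29 < 30; 30 is not < 1 ms
  expect_identical(flags[[2]], c(TRUE, FALSE))
})

test_that("both presets build and render without external input", {
  for (preset in c("electrode", "tetrode")) {
    cfg <- sim_config(preset, duration_s = 1.5, noise_n_trains = 40L,
                      seed = 5)
    sim <- simulate_recording(cfg)
    expect_identical(n_channels(sim$recording),
                     if (preset == "electrode") 1L else 4L)
    expect_identical(length(sim$truth$unit_times),
                     if (preset == "electrode") 2L else 3L)
    expect_equal(n_samples(sim$recording), 45000)
  }
})

test_that("expected spike counts scale linearly with duration", {
  cfg <- sim_config("electrode")
  set.seed(74)
  rates <- vapply(c(50, 100, 200), function(dur) {
    mean(vapply(1:8, function(i) {
      length(surrogate_train(dur, cfg, rate_hz = 8)) / dur
    }, 0))
  }, 0)
  expect_lt(max(rates) - min(rates), 0.6)  # within sampling error of equal
})

test_that("the overlap fraction grows with firing rate", {
  cfg <- sim_config("electrode", duration_s = 100)
  fr <- vapply(c(2, 8, 20), function(r) {
    set.seed(75)
    t1 <- round(surrogate_train(100, cfg, rate_hz = r) * 30000)
    t2 <- round(surrogate_train(100, cfg, rate_hz = r) * 30000)
    fl <- overlapsort:::overlap_flags(list(t1, t2), 30000)
    mean(unlist(fl))
  }, 0)
  expect_true(all(diff(fr) > 0))
})
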
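test_that("high-pass filtering rejects DC and preserves the passband", {
  fs <- 30000
  t <- seq_len(30000)
  dc <- raw_recording(rep(100, length(t)), fs)
  out <- highpass(dc, 300)
  expect_lt(max(abs(out$samples)), 1e-4)  # |out| < 1e-6 x input amplitude

  sine <- sin(2 * pi * 3000 * t / fs)
  out1 <- highpass(raw_recording(sine, fs), 300)
  mid <- 5000:25000
  # 3 kHz with a 300 Hz corner: amplitude preserved within 1 percent
  expect_lt(max(abs(out1$samples[1, mid] - sine[mid])), 0.01)

  # filtering twice barely changes an already-passband signal
  out2 <- highpass(out1, 300)
  expect_lt(max(abs(out2$samples[1, mid] - out1$samples[1, mid])) /
              max(abs(out1$samples[1, mid])), 0.02)
})

test_that("cutoffs at or above Nyquist are rejected", {
  rec <- raw_recording(rnorm(1000), 30000)
  expect_error(highpass(rec, 15000), "Nyquist")
})

test_that("noise SD estimators recover a known sigma", {
  expect_equal(estimate_noise_sd(raw_recording(rep(0, 2000), 30000)), 0)
  set.seed(11)
  x <- rnorm(1e6, 0, 3)
  rec <- raw_recording(x, 30000)
  expect_lt(abs(estimate_noise_sd(rec, "robust") - 3), 0.03)
  expect_lt(abs(estimate_noise_sd(rec, "plain") - 3), 0.03)
})

test_that("the robust estimator resists spike contamination", {
  set.seed(12)
  x <- rnorm(1e5, 0, 3)
  spike_at <- sample.int(1e5, 1000)  # 1 percent contamination
  x[spike_at] <- x[spike_at] - 50
  rec <- raw_recording(x, 30000)
  err_robust <- abs(estimate_noise_sd(rec, "robust") - 3)
  err_plain <- abs(estimate_noise_sd(rec, "plain") - 3)
  expect_lt(err_robust, err_plain)
  expect_lt(err_robust, 0.1)
})

test_that("a single pulse is detected at its trough, aligned at sample 11", {
  x <- gaussian_pulse_trace(3000, at = 1500, depth = 80, noise_sd = 5,
                            seed = 3)
  rec <- raw_recording(x, 30000)
  spikes <- detect_spikes(rec, detection_config(), threshold_uV = 20)
  expect_identical(n_spikes(spikes), 1L)
  expect_lte(abs(spikes$trigger_times - 1500), 1)
  # the waveform sample at local index 11 equals the trace at the trigger
  expect_equal(spikes$waveforms[1, 1, 11], x[spikes$trigger_times])
  expect_equal(min(spikes$waveforms[1, 1, ]), spikes$waveforms[1, 1, 11])
})

test_that("troughs 19 samples apart yield two spikes with shared samples", {
  x <- gaussian_pulse_trace(3000, at = 1500, depth = 80) +
    gaussian_pulse_trace(3000, at = 1519, depth = 60)
  spikes <- detect_spikes(raw_recording(x, 30000), detection_config(),
                          threshold_uV = 30)
  expect_identical(n_spikes(spikes), 2L)
  expect_identical(diff(spikes$trigger_times), 19L)
  # 32-sample windows 19 apart overlap by 13 samples
  w1_abs <- spikes$trigger_times[1] + (-10:21)
  w2_abs <- spikes$trigger_times[2] + (-10:21)
  expect_identical(length(intersect(w1_abs, w2_abs)), 13L)
})

test_that("a trace that never crosses threshold yields an empty spike set", {
  spikes <- detect_spikes(raw_recording(rnorm(5000, 0, 1), 30000),
                          detection_config(), threshold_uV = 50)
  expect_identical(n_spikes(spikes), 0L)
})

test_that("detection count is non-increasing in the threshold multiplier", {
  set.seed(21)
  x <- rnorm(60000, 0, 5)
  for (at in seq(2000, 58000, by = 2000)) {
    x <- x + gaussian_pulse_trace(60000, at, depth = runif(1, 30, 90))
  }
  rec <- raw_recording(x, 30000)
  counts <- vapply(c(2, 3, 4, 5, 6), function(k) {
    n_spikes(detect_spikes(rec, detection_config(threshold_multiplier = k)))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("boundary windows are discarded", {
  x <- gaussian_pulse_trace(100, at = 5, depth = 80)
  spikes <- detect_spikes(raw_recording(x, 30000), detection_config(),
                          threshold_uV = 30)
  expect_identical(n_spikes(spikes), 0L)
  expect_identical(attr(spikes, "n_boundary_discarded"), 1L)
})

test_that("multi-channel events merge to the deepest trough", {
  n <- 3000
  ch1 <- gaussian_pulse_trace(n, at = 1500, depth = 60)
  ch2 <- gaussian_pulse_trace(n, at = 1503, depth = 90)
  rec <- raw_recording(rbind(ch1, ch2), 30000)
  spikes <- detect_spikes(rec, detection_config(), threshold_uV = 30)
  expect_identical(n_spikes(spikes), 1L)
  expect_identical(spikes$trigger_times, 1503L)
  expect_identical(spikes$trigger_channels, 2L)
  # same window cut from both channels
  expect_equal(spikes$waveforms[1, 2, 11], min(ch2))
})

test_that("single-channel detection merged across channels matches the
           multi-channel path when only one channel crosses threshold", {
  n <- 6000
  ch1 <- gaussian_pulse_trace(n, at = 1000, depth = 80)
  ch2 <- gaussian_pulse_trace(n, at = 4000, depth = 70)
  rec <- raw_recording(rbind(ch1, ch2), 30000)
  multi <- detect_spikes(rec, detection_config(), threshold_uV = 30)
  t1 <- detect_spikes(raw_recording(ch1, 30000), detection_config(),
                      threshold_uV = 30)$trigger_times
  t2 <- detect_spikes(raw_recording(ch2, 30000), detection_config(),
                      threshold_uV = 30)$trigger_times
  expect_identical(multi$trigger_times, sort(c(t1, t2)))
})

test_that("polarity inversion detects positive spikes", {
  x <- -gaussian_pulse_trace(3000, at = 1500, depth = 80)
  spikes <- detect_spikes(raw_recording(x, 30000),
                          detection_config(invert_polarity = TRUE),
                          threshold_uV = 30)
  expect_identical(n_spikes(spikes), 1L)
  expect_equal(max(spikes$waveforms[1, 1, ]), spikes$waveforms[1, 1, 11])
})
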
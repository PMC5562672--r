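# hand-built bank rows exercise the scenario rules directly
toy_bank <- function(offset_a, offset_b, unit_a = 1L, unit_b = 2L) {
  tpl <- overlapsort:::electrode_sim_templates()
  wav <- array(tpl[[1]]$waveform, dim = c(1, 1, 32))
  list(waveforms = wav,
       meta = data.frame(id = 1L, unit_a = unit_a, unit_b = unit_b,
                         shift = abs(offset_b - offset_a),
                         trigger_in_superposition = 11L,
                         offset_a = offset_a, offset_b = offset_b,
                         trigger_channel = 1L))
}
match_row <- data.frame(spike_index = 1L, synthetic_id = 1L,
                        pearson_r = 0.9, cluster_id = 1L)
one_trough <- matrix(overlapsort:::electrode_sim_templates()[[1]]$waveform, 1)
two_trough <- one_trough
two_trough[1, 22:32] <- one_trough[1, 5:15]   # second deep minimum at 28

test_that("one in-window parent trigger means Scenario 1", {
  bank <- toy_bank(offset_a = -15L, offset_b = 10L)
  sc <- classify_scenario(match_row, bank, one_trough, 1L, 40)
  expect_identical(as.integer(sc), 1L)
  expect_identical(attr(sc, "dominant"), 2L)
  asg <- assign_overlap(match_row, sc, bank, trigger_time = 5000L)
  expect_identical(asg$assigned_units, 2L)
  expect_identical(asg$assigned_times, 5000L)
})

test_that("both triggers in-window with one threshold minimum is Scenario 2,
           assigning both units with offset-derived times", {
  bank <- toy_bank(offset_a = 10L, offset_b = 14L)
  sc <- classify_scenario(match_row, bank, one_trough, 1L, 40)
  expect_identical(as.integer(sc), 2L)
  asg <- assign_overlap(match_row, sc, bank, trigger_time = 10000L)
  expect_identical(asg$assigned_units, c(1L, 2L))
  expect_identical(asg$assigned_times, c(10000L - 1L, 10000L + 3L))
})

test_that("two threshold minima mean Scenario 3, assigned to the nearer
           parent trigger", {
  bank <- toy_bank(offset_a = 12L, offset_b = 4L)
  sc <- classify_scenario(match_row, bank, two_trough, 1L, 40)
  expect_identical(as.integer(sc), 3L)
  asg <- assign_overlap(match_row, sc, bank, trigger_time = 7000L)
  expect_identical(asg$assigned_units, 1L)   # |12-11| < |4-11|
  expect_identical(asg$assigned_times, 7000L)
})

test_that("the published worked example picks the nearer trigger", {
  # synthetic trigger at superposition sample 42, parents at 43 and 35:
  # in window coordinates (window starts at sample 32) these are local
  # offsets 11 (trigger), 12 and 4
  bank <- toy_bank(offset_a = 12L, offset_b = 4L, unit_a = 10L, unit_b = 20L)
  sc <- classify_scenario(match_row, bank, two_trough, 1L, 40)
  asg <- assign_overlap(match_row, sc, bank, trigger_time = 1L)
  expect_identical(asg$assigned_units, 10L)
})

test_that("a Scenario-3 tie goes to the deeper-trough template", {
  tpl <- overlapsort:::electrode_sim_templates()  # unit 1 deeper than unit 2
  bank <- toy_bank(offset_a = 8L, offset_b = 14L)  # both 3 from the trigger
  sc <- classify_scenario(match_row, bank, two_trough, 1L, 40)
  asg <- assign_overlap(match_row, sc, bank, trigger_time = 1L,
                        templates = tpl)
  expect_identical(asg$assigned_units, 1L)
})

test_that("both parents outside the window degrades to Scenario 1 with a
           warning", {
  bank <- toy_bank(offset_a = -5L, offset_b = 40L)
  expect_warning(sc <- classify_scenario(match_row, bank, one_trough, 1L, 40),
                 "outside")
  expect_identical(as.integer(sc), 1L)
  expect_identical(attr(sc, "dominant"), 1L)  # -5 is nearer 11 than 40
})

test_that("scenario classification is amplitude-scale invariant", {
  bank <- toy_bank(offset_a = 10L, offset_b = 14L)
  for (c_ in c(0.5, 1, 3)) {
    sc <- classify_scenario(match_row, bank, c_ * two_trough, 1L, c_ * 40)
    expect_identical(as.integer(sc), 3L)
  }
})

test_that("refractory cleanup demotes the lower-correlation member and
           leaves no sub-refractory interval", {
  fs <- 30000
  clean <- refractory_cleanup(list(data.frame(
    time = c(0, 60, 120), r_to_mean = c(0.9, 0.8, 0.9))), fs)
  expect_identical(nrow(clean$units[[1]]), 3L)
  expect_identical(nrow(clean$demoted), 0L)

  got <- refractory_cleanup(list(data.frame(
    time = c(1000, 1024), r_to_mean = c(0.99, 0.80))), fs)
  expect_equal(got$units[[1]]$time, 1000)
  expect_equal(got$demoted$time, 1024)

  # 0 / 0.6 / 1.2 ms with r 0.9 / 0.5 / 0.9: only the middle spike goes
  got3 <- refractory_cleanup(list(data.frame(
    time = c(0, 18, 36), r_to_mean = c(0.9, 0.5, 0.9))), fs)
  expect_equal(got3$units[[1]]$time, c(0, 36))
  expect_identical(nrow(got3$demoted), 1L)
})

test_that("cleanup matches a brute-force minimal-demotion oracle on small
           instances", {
  fs <- 30000
  refr <- 30
  legal <- function(times) length(times) < 2 || all(diff(sort(times)) >= refr)
  set.seed(60)
  for (trial in 1:40) {
    n <- sample(2:5, 1)
    times <- sort(sample.int(150, n))
    rs <- round(runif(n), 3)
    got <- refractory_cleanup(list(data.frame(time = times, r_to_mean = rs)),
                              fs)
    expect_true(legal(got$units[[1]]$time))
    # oracle: the largest subset that is legal
    best <- 0
    for (k in n:0) {
      if (k == 0) break
      combos <- utils::combn(n, k, simplify = FALSE)
      if (any(vapply(combos, function(ix) legal(times[ix]), TRUE))) {
        best <- k
        break
      }
    }
    # chronological scanning keeps at least one fewer than the optimum
    expect_gte(nrow(got$units[[1]]), best - 1L)
    expect_identical(nrow(got$units[[1]]) + nrow(got$demoted), n)
  }
})
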
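test_that("degenerate and deterministic generation contracts hold", {
  # no tonic activity and no bursts -> silent well
  s0 <- network_spec(tonic_rate_hz = 0, nb_rate_per_min = 0, seed = 5)
  r0 <- simulate_well(s0)
  expect_equal(nrow(r0$well$spikes), 0)
  expect_equal(nrow(r0$truth$windows), 0)

  s <- network_spec(seed = 11)
  r1 <- simulate_well(s)
  r2 <- simulate_well(s)
  expect_identical(r1$well$spikes, r2$well$spikes)
  expect_identical(r1$truth$windows, r2$truth$windows)
})

test_that("spec validation rejects out-of-range fields by name", {
  expect_error(network_spec(duration_s = -1), "duration_s")
  expect_error(network_spec(participation_frac = 0), "participation_frac")
  expect_error(network_spec(participation_frac = 1.2), "participation_frac")
  expect_error(network_spec(tonic_rate_hz = -0.1), "tonic_rate_hz")
  expect_error(network_spec(inhibitory_fraction = 0.5),
               "inhibitory_fraction")
  # 30 bursts/min of 1900 ms leaves a mean gap of 100 ms < 200 ms
  expect_error(network_spec(nb_rate_per_min = 30, nb_duration_ms = 1900),
               "gap")
})

test_that("planted window count matches the renewal-process expectation", {
  # renewal with exponential gaps (mean 4.8 s) and gamma durations:
  # E[N] = 600 / 6 = 100, Var[N] ~ t * var(interval) / mean(interval)^3
  s <- network_spec(nb_rate_per_min = 10, nb_duration_ms = 1200,
                    nb_duration_cv = 0.25, seed = 42)
  var_interval <- 4.8^2 + (1.2 * 0.25)^2
  sd_n <- sqrt(600 * var_interval / 6^3)
  n <- nrow(simulate_well(s)$truth$windows)
  expect_gt(n, 100 - 3 * sd_n)
  expect_lt(n, 100 + 3 * sd_n)
  # windows never overlap and stay inside the recording
  w <- simulate_well(s)$truth$windows
  expect_true(all(w$end_s > w$start_s))
  expect_true(all(diff(w$start_s) > 0))
  expect_true(all(w$start_s[-1] >= w$end_s[-nrow(w)]))
  expect_true(all(w$end_s <= 600))
})

test_that("planted tonic rate and spike labels are consistent", {
  s <- network_spec(tonic_rate_hz = 0.5, nb_rate_per_min = 5,
                    nb_duration_ms = 600, seed = 7)
  r <- simulate_well(s)
  truth <- r$truth
  # every spike within the well, in-burst spikes inside their window
  expect_true(all(truth$spikes$time_s >= 0 & truth$spikes$time_s <= 600))
  bursty <- truth$spikes[truth$spikes$label == "burst", ]
  jit_slack <- 6 * s$onset_jitter_ms / 1000
  expect_true(all(
    bursty$time_s >= truth$windows$start_s[bursty$window] - jit_slack &
      bursty$time_s <= truth$windows$end_s[bursty$window] + jit_slack))
  # per-channel tonic counts within 3 Poisson SDs of rate * duration
  tonic <- truth$spikes[truth$spikes$label == "tonic", ]
  expected <- 0.5 * 600
  for (ch in unique(tonic$channel_id)) {
    n_ch <- sum(tonic$channel_id == ch)
    expect_lt(abs(n_ch - expected), 3 * sqrt(expected))
  }
})

test_that("the inhibitory-fraction map is strictly monotone and paired", {
  base <- network_spec(seed = 3)
  series <- simulate_ei_series(base, c(0, 0.05, 0.25, 0.35))
  expect_length(series, 4)
  nbd <- vapply(series, function(r) r$truth$spec$nb_duration_ms, 0)
  inr <- vapply(series, function(r) r$truth$spec$in_burst_rate_hz, 0)
  ton <- vapply(series, function(r) r$truth$spec$tonic_rate_hz, 0)
  expect_true(all(diff(nbd) < 0))
  expect_true(all(diff(inr) < 0))
  expect_true(all(diff(ton) > 0))
  # endpoint check: planted NBD at 0.35 below planted NBD at 0
  expect_lt(nbd[4], nbd[1])

  expect_identical(simulate_ei_series(base, numeric(0)), list())
  expect_error(simulate_ei_series(base, c(-0.1, 0.2)), "fraction")
  expect_error(simulate_ei_series(base, c(0.2, 0.1)), "ascending")
})

test_that("synthetic raw traces carry calibrated noise and exact templates", {
  tpl <- spike_template(10000, peak_amplitude = 8)
  # pure noise: sample SD within 2% of the requested SD over 600 s
  tr <- simulate_raw_trace(numeric(0), tpl, noise_sd = 1, duration_s = 600,
                           seed = 2)
  expect_lt(abs(sd(tr$samples) - 1), 0.02)
  # zero noise, one template: trace equals the template at the offset
  tr0 <- simulate_raw_trace(1.0, tpl, noise_sd = 0, duration_s = 2, seed = 2)
  pk <- attr(tpl, "peak_index")
  i0 <- round(1.0 * 10000) + 1 - (pk - 1)
  expect_equal(tr0$samples[i0:(i0 + length(tpl) - 1)], as.numeric(tpl))
  expect_true(all(tr0$samples[-(i0:(i0 + length(tpl) - 1))] == 0))
  # planted 8-SD peaks all clear a 4.5-SD threshold by construction
  expect_gt(max(abs(tpl)), 4.5)
  # overlapping templates warn but still superpose
  expect_warning(simulate_raw_trace(c(0.5, 0.5005), tpl, 0, 2, seed = 1),
                 "overlap")
})

test_that("PSC decay mixtures match the truncated-normal tail probability", {
  ev <- simulate_psc_events(10000, 10000, glu_decay = c(2.0, 0.5),
                            gaba_decay = c(7.0, 1.5), seed = 9)
  expect_equal(nrow(ev), 20000)
  expect_true(all(ev$decay_ms > 0))
  expect_false(is.unsorted(ev$time_s))
  # fraction of glutamatergic draws above 3.8 ms vs the closed-form
  # truncated-normal tail: P(X > 3.8 | X > 0)
  glu <- ev$decay_ms[ev$true_class == "glutamatergic"]
  tail_exp <- pnorm(3.8, 2, 0.5, lower.tail = FALSE) /
    pnorm(0, 2, 0.5, lower.tail = FALSE)
  expect_lt(abs(mean(glu > 3.8) - tail_exp), 0.01)
  # determinism and class-only streams
  expect_identical(ev, simulate_psc_events(10000, 10000, seed = 9))
  only_gaba <- simulate_psc_events(0, 50, seed = 1)
  expect_true(all(only_gaba$true_class == "GABAergic"))
  expect_error(simulate_psc_events(-1, 5), "non-negative")
})
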
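test_that("feature arithmetic matches hand-computed wells", {
  # one channel, 600 evenly spread spikes, no bursts possible
  w <- mea_well("W", 600, data.frame(channel_id = "c1",
                                     time_s = seq(0.5, 599.5, by = 1)))
  f <- compute_features(w)
  expect_equal(f$mfr_hz, 1.0)
  expect_equal(f$prs_pct, 100)
  expect_equal(f$nbr_per_min, 0)
  expect_true(is.na(f$nbd_ms))
  expect_true(is.na(f$nibi_s))

  # constructed detection output: 80 of 100 spikes inside bursts -> PRS 20%
  t_burst <- 10 + (0:79) * 0.01               # one 80-spike burst
  t_rand <- seq(100, 575, by = 25)            # 20 isolated spikes
  w2 <- mea_well("W2", 600, data.frame(channel_id = "c1",
                                       time_s = c(t_burst, t_rand)))
  f2 <- compute_features(w2)
  expect_equal(f2$n_spikes, 100L)
  expect_equal(f2$prs_pct, 20)

  # 50 planted network bursts of 400 ms in 10 min -> NBR 5/min, NBD 400 ms
  nb <- data.frame(start_s = seq(10, 10 + 49 * 11, by = 11))
  nb$end_s <- nb$start_s + 0.4
  nb$n_channels <- 2L
  nb$n_spikes <- 0L
  nb$channels <- replicate(50, c("c1"), simplify = FALSE)
  class(nb) <- c("mea_network_bursts", "data.frame")
  f3 <- compute_features(w, bursts = detect_well_bursts(w),
                         network_bursts = nb)
  expect_equal(f3$nbr_per_min, 5)
  expect_equal(f3$nbd_ms, 400)
  expect_equal(f3$nibi_s, 10.6)

  # an empty well reports everything missing
  f0 <- compute_features(mea_well("E", 600, NULL, channels = "c1"))
  expect_true(is.na(f0$mfr_hz))
  expect_true(is.na(f0$prs_pct))
})

test_that("random and non-random spike percentages partition exactly", {
  s <- network_spec(nb_rate_per_min = 5, nb_duration_ms = 800,
                    tonic_rate_hz = 0.5, seed = 13)
  r <- simulate_well(s)
  p <- burst_params()
  b <- detect_well_bursts(r$well, p)
  nb <- detect_network_bursts(r$well, b, p)
  f <- compute_features(r$well, b, nb, p)
  # recount the non-random side independently
  spk <- r$well$spikes
  nonrandom <- rep(FALSE, nrow(spk))
  for (i in seq_len(nrow(b))) {
    nonrandom <- nonrandom | (spk$channel_id == b$channel_id[i] &
                                spk$time_s >= b$start_s[i] &
                                spk$time_s <= b$end_s[i])
  }
  for (i in seq_len(nrow(nb))) {
    nonrandom <- nonrandom | (spk$time_s >= nb$start_s[i] &
                                spk$time_s <= nb$end_s[i])
  }
  expect_equal(f$prs_pct + 100 * mean(nonrandom), 100)
})

test_that("burst shapes align, bin and average as defined", {
  # one burst, 10 spikes in the first 10 ms, 10 ms bins
  w <- mea_well("W", 10, data.frame(channel_id = "c1",
                                    time_s = 1 + (0:9) * 0.001))
  nb <- data.frame(start_s = 1, end_s = 1.05, n_channels = 1L,
                   n_spikes = 10L)
  nb$channels <- list("c1")
  shp <- burst_shape(w, nb, bin_width_ms = 10)
  expect_equal(shp$mean_profile, c(10, 0, 0, 0, 0))
  expect_equal(rowSums(shp$counts), 10)

  # two identical bursts: the mean profile equals either row
  w2 <- mea_well("W", 10, data.frame(
    channel_id = "c1", time_s = c(1 + (0:9) * 0.001, 5 + (0:9) * 0.001)))
  nb2 <- data.frame(start_s = c(1, 5), end_s = c(1.05, 5.05),
                    n_channels = 1L, n_spikes = 10L)
  nb2$channels <- list("c1", "c1")
  shp2 <- burst_shape(w2, nb2, bin_width_ms = 10)
  expect_equal(shp2$mean_profile, shp2$counts[1, ])
  expect_equal(shp2$counts[1, ], shp2$counts[2, ])

  # no network bursts -> empty, flagged shape
  empty <- burst_shape(w, NULL)
  expect_equal(empty$n_bursts, 0)

  # flat planted in-burst rate -> flat mean profile (3 Poisson SDs per bin)
  s <- network_spec(nb_rate_per_min = 6, nb_duration_ms = 500,
                    nb_duration_cv = 0, tonic_rate_hz = 0,
                    onset_jitter_ms = 0, seed = 17)
  r <- simulate_well(s)
  nbs <- detect_network_bursts(r$well)
  shp3 <- burst_shape(r$well, nbs, bin_width_ms = 50)
  # expected spikes per 50 ms bin: 12 channels x 150 Hz x 0.05 s
  expected <- 12 * 150 * 0.05
  inner <- shp3$mean_profile[2:(length(shp3$mean_profile) - 2)]
  tol <- 3 * sqrt(expected / shp3$n_bursts)
  expect_true(all(abs(inner - expected) < tol))
})

test_that("the Holm-Sidak step-down procedure matches its oracle", {
  # m = 1: the adjusted threshold is alpha itself
  hs1 <- holm_sidak(0.049, alpha = 0.05)
  expect_equal(hs1$thresholds, 0.05)
  expect_true(hs1$significant)
  expect_false(holm_sidak(0.051, alpha = 0.05)$significant)

  # m = 10, smallest p = 0.004: step-1 threshold 1 - 0.95^(1/10)
  p10 <- c(0.004, seq(0.2, 0.9, length.out = 9))
  hs10 <- holm_sidak(p10, alpha = 0.05)
  expect_equal(hs10$thresholds[1], 1 - 0.95^(1 / 10))
  expect_gt(hs10$thresholds[1], 0.004)
  expect_true(hs10$significant[1])
  expect_false(any(hs10$significant[-1]))

  # brute-force equivalence on random p-vectors, m <= 20
  set.seed(23)
  for (i in 1:200) {
    m <- sample.int(20, 1)
    p <- runif(m)^sample(c(1, 2, 4), 1)  # push some p small
    expect_identical(holm_sidak(p, 0.05)$significant,
                     brute_holm_sidak(p, 0.05))
  }
})

test_that("per-bin group comparison flags only real differences", {
  set.seed(31)
  # identical generating distribution: nothing significant
  a <- matrix(rpois(8 * 12, 20), nrow = 8)
  cmp0 <- compare_shapes(a, a + 0L * a, alpha = 0.05)
  expect_false(any(cmp0$significant))

  b <- matrix(rpois(8 * 12, 20), nrow = 8)
  b[, 3] <- b[, 3] + 40 # one strongly shifted bin
  cmp <- compare_shapes(a, b, alpha = 0.05)
  expect_true(cmp$significant[3])
  expect_equal(sum(cmp$significant), 1)

  expect_error(compare_shapes(a[1, , drop = FALSE], b), "two wells")
  # mismatched bin widths between shape lists are rejected
  w <- mea_well("W", 10, data.frame(channel_id = "c1",
                                    time_s = 1 + (0:9) * 0.001))
  nb <- data.frame(start_s = 1, end_s = 1.05, n_channels = 1L,
                   n_spikes = 10L)
  nb$channels <- list("c1")
  s10 <- list(burst_shape(w, nb, 10), burst_shape(w, nb, 10))
  s20 <- list(burst_shape(w, nb, 20), burst_shape(w, nb, 20))
  expect_error(compare_shapes(s10, s20), "bin width")
})

test_that("measured features scale with the planted inhibitory fraction", {
  fractions <- c(0, 0.35)
  seeds <- 1:6
  nbd <- mfr <- prs <- matrix(NA_real_, length(seeds), length(fractions))
  for (k in seq_along(seeds)) {
    base <- network_spec(duration_s = 300, seed = seeds[k])
    series <- simulate_ei_series(base, fractions)
    for (j in seq_along(series)) {
      f <- compute_features(series[[j]]$well)
      nbd[k, j] <- f$nbd_ms; mfr[k, j] <- f$mfr_hz; prs[k, j] <- f$prs_pct
    }
  }
  m <- function(x) colMeans(x)
  expect_lt(m(nbd)[2], m(nbd)[1])
  expect_lt(m(mfr)[2], m(mfr)[1])
  expect_gt(m(prs)[2], m(prs)[1])
})
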
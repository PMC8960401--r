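#' Specification of a synthetic E/I network well
#'
#' Describes the generative model for one simulated MEA well: per-channel
#' tonic (background) Poisson spiking plus network-wide bursts drawn from a
#' renewal process. Network-burst onsets are separated by exponential gaps,
#' durations are gamma-distributed, and within each burst every recruited
#' channel fires as a Poisson process at `in_burst_rate_hz`, with its onset
#' shifted by Gaussian jitter. The `inhibitory_fraction` knob is carried as
#' metadata; [simulate_ei_series()] maps it onto burst duration, in-burst
#' rate and tonic rate.
#'
#' @param n_channels electrodes per well (default 12, the 24-well MEA layout).
#' @param duration_s recording length in seconds (default 600, i.e. 10 min).
#' @param tonic_rate_hz per-channel background Poisson rate (Hz).
#' @param nb_rate_per_min planted network-burst rate (bursts/min).
#' @param nb_duration_ms planted mean network-burst duration (ms).
#' @param nb_duration_cv coefficient of variation of burst durations.
#' @param in_burst_rate_hz per-channel firing rate inside a network burst (Hz).
#' @param participation_frac probability that a channel is recruited into a
#'   given network burst, in (0, 1].
#' @param onset_jitter_ms SD of the Gaussian per-channel burst-onset jitter (ms).
#' @param inhibitory_fraction inhibitory-neuron fraction knob in [0, 0.35].
#' @param seed integer seed; all randomness derives from it.
#' @return An object of class `network_spec`.
#' @details The generator refuses specifications whose mean inter-burst gap
#'   (onset-to-onset interval minus mean duration) is below 200 ms: such
#'   bursts would be merged by the downstream 65 ms rule and the planted
#'   ground truth would stop being identifiable.
#' @export
network_spec <- function(n_channels = 12, duration_s = 600,
                         tonic_rate_hz = 0.3, nb_rate_per_min = 10,
                         nb_duration_ms = 1200, nb_duration_cv = 0.25,
                         in_burst_rate_hz = 150, participation_frac = 1,
                         onset_jitter_ms = 5, inhibitory_fraction = 0,
                         seed = 1L) {
  spec <- structure(
    list(n_channels = as.integer(n_channels), duration_s = duration_s,
         tonic_rate_hz = tonic_rate_hz, nb_rate_per_min = nb_rate_per_min,
         nb_duration_ms = nb_duration_ms, nb_duration_cv = nb_duration_cv,
         in_burst_rate_hz = in_burst_rate_hz,
         participation_frac = participation_frac,
         onset_jitter_ms = onset_jitter_ms,
         inhibitory_fraction = inhibitory_fraction, seed = as.integer(seed)),
    class = "network_spec"
  )
  validate_network_spec(spec)
  spec
}

validate_network_spec <- function(spec) {
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid network_spec: %s %s", field, msg),
                  call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  chk(num1(spec$duration_s) && spec$duration_s > 0, "duration_s",
      "must be > 0")
  chk(is.integer(spec$n_channels) && spec$n_channels >= 1, "n_channels",
      "must be a positive integer")
  for (f in c("tonic_rate_hz", "nb_rate_per_min", "nb_duration_ms",
              "nb_duration_cv", "in_burst_rate_hz", "onset_jitter_ms")) {
    chk(num1(spec[[f]]) && spec[[f]] >= 0, f, "must be >= 0")
  }
  chk(num1(spec$participation_frac) && spec$participation_frac > 0 &&
        spec$participation_frac <= 1, "participation_frac",
      "must be in (0, 1]")
  chk(num1(spec$inhibitory_fraction) && spec$inhibitory_fraction >= 0 &&
        spec$inhibitory_fraction <= 0.35, "inhibitory_fraction",
      "must be in [0, 0.35]")
  if (spec$nb_rate_per_min > 0) {
    mean_gap_s <- 60 / spec$nb_rate_per_min - spec$nb_duration_ms / 1000
    chk(mean_gap_s >= 0.2, "nb_rate_per_min/nb_duration_ms",
        sprintf("leave a mean inter-burst gap of %.0f ms (< 200 ms)",
                mean_gap_s * 1000))
  }
  invisible(spec)
}

#' Simulate one MEA well with planted network bursts
#'
#' Draws network-burst windows from a renewal process (exponential
#' end-to-next-onset gaps at the rate implied by `nb_rate_per_min`, gamma
#' durations), then populates every channel from its own RNG sub-stream:
#' tonic Poisson spikes over the whole recording, plus in-burst Poisson
#' spikes within each window the channel is recruited into, the channel's
#' window onset shifted by Gaussian jitter. Because each channel consumes an
#' independent sub-stream, raising `n_channels` leaves the spike trains of
#' existing channels unchanged.
#'
#' @param spec a [network_spec()].
#' @param well_id well label for the returned recording.
#' @param metadata optional metadata list stored on the well; the planted
#'   `inhibitory_fraction` is always added.
#' @return A list with elements `well` (an [mea_well()]) and `truth`
#'   (class `mea_ground_truth`: the planted window table with recruited
#'   channel sets, the labelled spike table, and the spec).
#' @export
simulate_well <- function(spec, well_id = "W1", metadata = list()) {
  validate_network_spec(spec)
  windows <- with_seed(derive_seed(spec$seed, 0), plant_windows(spec))
  n_win <- nrow(windows)

  spk <- vector("list", spec$n_channels)
  recruit <- matrix(FALSE, nrow = n_win, ncol = spec$n_channels)
  for (ch in seq_len(spec$n_channels)) {
    res <- with_seed(derive_seed(spec$seed, ch),
                     plant_channel(spec, windows))
    spk[[ch]] <- res$spikes
    if (n_win) recruit[, ch] <- res$recruited
  }
  chan_ids <- sprintf("ch%02d", seq_len(spec$n_channels))
  labelled <- do.call(rbind, lapply(seq_len(spec$n_channels), function(ch) {
    s <- spk[[ch]]
    if (!nrow(s)) return(s)
    s$channel_id <- chan_ids[ch]
    s
  }))
  if (is.null(labelled) || !nrow(labelled)) {
    labelled <- data.frame(time_s = numeric(), label = character(),
                           window = integer(), channel_id = character())
  }
  labelled <- labelled[order(labelled$channel_id, labelled$time_s),
                       c("channel_id", "time_s", "label", "window")]
  rownames(labelled) <- NULL

  windows$channels <- I(lapply(seq_len(n_win),
                               function(w) chan_ids[recruit[w, ]]))
  metadata$inhibitory_fraction <- spec$inhibitory_fraction
  well <- mea_well(well_id, spec$duration_s,
                   labelled[, c("channel_id", "time_s")],
                   channels = chan_ids, metadata = metadata)
  truth <- structure(list(windows = windows, spikes = labelled, spec = spec),
                     class = "mea_ground_truth")
  list(well = well, truth = truth)
}

# renewal process of non-overlapping windows on [0, duration]
plant_windows <- function(spec) {
  empty <- data.frame(start_s = numeric(), end_s = numeric())
  if (spec$nb_rate_per_min <= 0) return(empty)
  mean_dur_s <- spec$nb_duration_ms / 1000
  mean_gap_s <- 60 / spec$nb_rate_per_min - mean_dur_s
  cv <- spec$nb_duration_cv
  rdur <- function(n) {
    if (cv <= 0 || mean_dur_s <= 0) return(rep(mean_dur_s, n))
    shape <- 1 / cv^2
    stats::rgamma(n, shape = shape, rate = shape / mean_dur_s)
  }
  starts <- numeric(0); ends <- numeric(0)
  t <- stats::rexp(1, rate = 1 / mean_gap_s)
  repeat {
    d <- rdur(1)
    if (t + d > spec$duration_s) break
    starts <- c(starts, t); ends <- c(ends, t + d)
    t <- t + d + stats::rexp(1, rate = 1 / mean_gap_s)
  }
  data.frame(start_s = starts, end_s = ends)
}

# one channel's spikes and per-window recruitment, from its own stream
plant_channel <- function(spec, windows) {
  n_win <- nrow(windows)
  recruited <- if (n_win) {
    stats::runif(n_win) <= spec$participation_frac
  } else logical(0)
  jit <- if (n_win) {
    stats::rnorm(n_win, 0, spec$onset_jitter_ms / 1000)
  } else numeric(0)

  n_tonic <- stats::rpois(1, spec$tonic_rate_hz * spec$duration_s)
  parts <- vector("list", n_win + 1L)
  parts[[1L]] <- data.frame(time_s = sort(stats::runif(n_tonic, 0,
                                                       spec$duration_s)),
                            label = rep("tonic", n_tonic),
                            window = rep(NA_integer_, n_tonic))
  for (w in seq_len(n_win)) {
    if (!recruited[w]) next
    a <- max(0, windows$start_s[w] + jit[w])
    b <- min(spec$duration_s, windows$end_s[w] + jit[w])
    if (b <= a) next
    n_in <- stats::rpois(1, spec$in_burst_rate_hz * (b - a))
    if (n_in) {
      parts[[w + 1L]] <- data.frame(time_s = sort(stats::runif(n_in, a, b)),
                                    label = "burst", window = w)
    }
  }
  list(spikes = do.call(rbind, parts[!vapply(parts, is.null, logical(1))]),
       recruited = recruited)
}

#' Simulate a titration series over the inhibitory fraction
#'
#' Produces one well per requested inhibitory fraction. The planted network
#' burst duration and in-burst rate decrease linearly, and the tonic rate
#' increases linearly, from their values at fraction 0 to their values at
#' fraction 0.35; all other fields (including the seed) are copied from
#' `base`, so wells in a series are paired draws.
#'
#' @param base a [network_spec()] providing every non-mapped field.
#' @param inhibitory_fractions ascending vector of fractions in [0, 0.35].
#' @param endpoints named list with elements `nb_duration_ms`,
#'   `in_burst_rate_hz`, `tonic_rate_hz`, each a length-2 vector giving the
#'   planted value at fraction 0 and at fraction 0.35.
#' @return A list with one element per fraction, each as returned by
#'   [simulate_well()].
#' @export
simulate_ei_series <- function(base, inhibitory_fractions,
                               endpoints = list(
                                 nb_duration_ms = c(1200, 300),
                                 in_burst_rate_hz = c(150, 60),
                                 tonic_rate_hz = c(0.3, 0.8))) {
  stopifnot(inherits(base, "network_spec"))
  f <- inhibitory_fractions
  if (!length(f)) return(list())
  if (any(!is.finite(f)) || any(f < 0) || any(f >= 1)) {
    stop("inhibitory fractions must lie in [0, 1)", call. = FALSE)
  }
  if (any(f > 0.35)) {
    stop("inhibitory fractions must lie in [0, 0.35]", call. = FALSE)
  }
  if (is.unsorted(f, strictly = TRUE)) {
    stop("inhibitory fractions must be sorted ascending", call. = FALSE)
  }
  lerp <- function(ends, x) ends[1] + (ends[2] - ends[1]) * x / 0.35
  lapply(seq_along(f), function(i) {
    spec <- base
    spec$inhibitory_fraction <- f[i]
    spec$nb_duration_ms <- lerp(endpoints$nb_duration_ms, f[i])
    spec$in_burst_rate_hz <- lerp(endpoints$in_burst_rate_hz, f[i])
    spec$tonic_rate_hz <- lerp(endpoints$tonic_rate_hz, f[i])
    validate_network_spec(spec)
    simulate_well(spec, well_id = sprintf("EI%02d", i),
                  metadata = list(inhibitory_fraction = f[i]))
  })
}

#' Biphasic extracellular spike template
#'
#' A short biphasic waveform (negative trough followed by a smaller positive
#' rebound) used to plant spikes in synthetic raw traces. The sample index of
#' its dominant (negative) peak is returned as attribute `peak_index` so
#' templates can be planted peak-aligned.
#'
#' @param sampling_rate_hz sampling rate in Hz.
#' @param peak_amplitude absolute amplitude of the dominant trough (same
#'   units as the trace, conventionally µV).
#' @param duration_ms template length in ms.
#' @return Numeric waveform with attribute `peak_index`.
#' @export
spike_template <- function(sampling_rate_hz = 10000, peak_amplitude = 8,
                           duration_ms = 1.5) {
  n <- max(3L, round(duration_ms / 1000 * sampling_rate_hz))
  t <- seq(0, 1, length.out = n)
  w <- -sin(pi * t)^2 * sin(2 * pi * t * 1.5)
  w <- w / max(abs(w)) * peak_amplitude
  structure(w, peak_index = which.max(abs(w)))
}

#' Synthesise a raw extracellular trace from spike times
#'
#' Gaussian noise of SD `noise_sd` with `template` superimposed, peak-aligned,
#' at every spike time. Overlapping templates are summed (with a warning when
#' two spikes are closer than the template length).
#'
#' @param spike_times_s spike times in seconds.
#' @param template waveform from [spike_template()] (or any numeric vector;
#'   peak alignment then uses its largest-magnitude sample).
#' @param noise_sd SD of the additive Gaussian noise.
#' @param duration_s trace length in seconds.
#' @param sampling_rate_hz sampling rate (default 10 kHz).
#' @param channel_id channel label of the returned trace.
#' @param seed RNG seed for the noise.
#' @return A `raw_trace` (see [raw_trace()]).
#' @export
simulate_raw_trace <- function(spike_times_s, template, noise_sd,
                               duration_s, sampling_rate_hz = 10000,
                               channel_id = "ch01", seed = 1L) {
  if (length(spike_times_s) &&
      (min(spike_times_s) < 0 || max(spike_times_s) >= duration_s)) {
    stop("spike times must lie within [0, duration_s)", call. = FALSE)
  }
  n <- round(duration_s * sampling_rate_hz)
  x <- if (noise_sd > 0) {
    with_seed(derive_seed(seed, 99), stats::rnorm(n, 0, noise_sd))
  } else numeric(n)
  tpl <- as.numeric(template)
  pk <- attr(template, "peak_index")
  if (is.null(pk)) pk <- which.max(abs(tpl))
  st <- sort(spike_times_s)
  if (length(st) > 1 &&
      any(diff(st) * sampling_rate_hz < length(tpl))) {
    warning("templates overlap (spikes closer than the template length); ",
            "superposition applied", call. = FALSE)
  }
  for (ts in st) {
    i0 <- round(ts * sampling_rate_hz) + 1L - (pk - 1L)
    idx <- seq.int(i0, i0 + length(tpl) - 1L)
    keep <- idx >= 1L & idx <= n
    x[idx[keep]] <- x[idx[keep]] + tpl[keep]
  }
  raw_trace(channel_id, x, sampling_rate_hz)
}

#' Simulate a two-population postsynaptic-current event stream
#'
#' Glutamatergic and GABAergic events carry decay times drawn from
#' zero-truncated normal distributions; event times are Poisson (uniform
#' order statistics) on the recording, amplitudes log-normal.
#'
#' @param n_glu,n_gaba event counts per class (non-negative).
#' @param glu_decay,gaba_decay length-2 vectors `c(mean_ms, sd_ms)` of the
#'   decay-time distributions before truncation at 0.
#' @param duration_s recording length used for event times.
#' @param seed RNG seed.
#' @return data.frame with `time_s`, `amplitude_pA`, `decay_ms`, `true_class`,
#'   sorted by time.
#' @export
simulate_psc_events <- function(n_glu, n_gaba,
                                glu_decay = c(2.0, 0.5),
                                gaba_decay = c(7.0, 1.5),
                                duration_s = 120, seed = 1L) {
  if (length(n_glu) != 1 || length(n_gaba) != 1 || n_glu < 0 || n_gaba < 0) {
    stop("event counts must be non-negative", call. = FALSE)
  }
  if (glu_decay[1] <= 0 || gaba_decay[1] <= 0) {
    stop("decay means must be > 0", call. = FALSE)
  }
  rtruncnorm0 <- function(n, mean, sd) {
    if (n == 0) return(numeric(0))
    if (sd <= 0) return(rep(mean, n))
    lo <- stats::pnorm(0, mean, sd)
    stats::qnorm(stats::runif(n, lo, 1), mean, sd)
  }
  with_seed(derive_seed(seed, 7), {
    n <- n_glu + n_gaba
    ev <- data.frame(
      time_s = stats::runif(n, 0, duration_s),
      amplitude_pA = stats::rlnorm(n, log(30), 0.4),
      decay_ms = c(rtruncnorm0(n_glu, glu_decay[1], glu_decay[2]),
                   rtruncnorm0(n_gaba, gaba_decay[1], gaba_decay[2])),
      true_class = rep(c("glutamatergic", "GABAergic"), c(n_glu, n_gaba)))
    ev <- ev[order(ev$time_s), , drop = FALSE]
    rownames(ev) <- NULL
    ev
  })
}
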
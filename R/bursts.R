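#' Burst and network-burst detection parameters
#'
#' Defaults are the standard multiwell analysis settings: bursts are maximal
#' spike runs with inter-spike intervals of at most 30 ms, bursts less than
#' 65 ms apart are merged, and merged bursts shorter than 50 ms or with
#' fewer than 4 spikes are discarded. A network burst requires simultaneous
#' bursting on more than 80% of the active channels, where a channel is
#' active when its mean firing rate exceeds 0.1 Hz.
#'
#' @param max_isi_ms maximum in-burst inter-spike interval (ms).
#' @param merge_gap_ms bursts closer than this gap (end to next start) merge.
#' @param min_duration_ms minimum burst duration kept (ms).
#' @param min_spikes minimum spike count kept.
#' @param nb_channel_fraction network-burst coincidence fraction in (0, 1).
#' @param active_mfr_hz activity threshold on the per-channel firing rate.
#' @return An object of class `burst_params`.
#' @export
burst_params <- function(max_isi_ms = 30, merge_gap_ms = 65,
                         min_duration_ms = 50, min_spikes = 4,
                         nb_channel_fraction = 0.8, active_mfr_hz = 0.1) {
  p <- list(max_isi_ms = max_isi_ms, merge_gap_ms = merge_gap_ms,
            min_duration_ms = min_duration_ms, min_spikes = min_spikes,
            nb_channel_fraction = nb_channel_fraction,
            active_mfr_hz = active_mfr_hz)
  for (f in names(p)) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]) ||
        p[[f]] <= 0) {
      stop(sprintf("burst_params: '%s' must be a single positive number", f),
           call. = FALSE)
    }
  }
  if (p$nb_channel_fraction >= 1) {
    stop("burst_params: 'nb_channel_fraction' must be in (0, 1)",
         call. = FALSE)
  }
  structure(p, class = "burst_params")
}

# fp guard for ms-scale boundary comparisons on second-scale floats
.ms_eps <- 1e-9

#' Detect bursts on a single spike train
#'
#' Three fixed stages. Detect: maximal runs of consecutive spikes whose
#' every inter-spike interval is at most `max_isi_ms` (a 30 ms interval
#' still continues the burst) become candidates spanning first to last
#' spike. Merge: consecutive candidates whose gap (next start minus previous
#' end) is strictly below `merge_gap_ms` are merged transitively. Filter:
#' candidates shorter than `min_duration_ms` or with fewer than `min_spikes`
#' spikes are discarded.
#'
#' @param spike_times_s sorted spike times in seconds (or a `spike_train`).
#' @param params a [burst_params()].
#' @return data.frame with `start_s`, `end_s`, `n_spikes`; start and end
#'   coincide with spike times.
#' @export
detect_bursts <- function(spike_times_s, params = burst_params()) {
  if (inherits(spike_times_s, "spike_train")) {
    spike_times_s <- spike_times_s$spike_times_s
  }
  t <- as.numeric(spike_times_s)
  if (is.unsorted(t)) stop("spike times must be sorted", call. = FALSE)
  empty <- data.frame(start_s = numeric(), end_s = numeric(),
                      n_spikes = integer())
  if (!length(t)) return(empty)

  # stage 1: split at ISIs exceeding the maximum (inclusive boundary)
  brk <- which(diff(t) * 1000 > params$max_isi_ms + .ms_eps)
  s_idx <- c(1L, brk + 1L)
  e_idx <- c(brk, length(t))
  start <- t[s_idx]; end <- t[e_idx]; n <- e_idx - s_idx + 1L

  # stage 2: transitive merge of candidates separated by < merge_gap_ms
  if (length(start) > 1) {
    gap_ms <- (start[-1] - end[-length(end)]) * 1000
    grp <- cumsum(c(1L, as.integer(gap_ms >= params$merge_gap_ms - .ms_eps)))
    start <- as.numeric(tapply(start, grp, min))
    end <- as.numeric(tapply(end, grp, max))
    n <- as.integer(tapply(n, grp, sum))
  }

  # stage 3: duration / spike-count filter
  keep <- (end - start) * 1000 >= params$min_duration_ms - .ms_eps &
    n >= params$min_spikes
  out <- data.frame(start_s = start[keep], end_s = end[keep],
                    n_spikes = n[keep])
  rownames(out) <- NULL
  out
}

#' Detect bursts on every channel of a well
#'
#' @param well an [mea_well()].
#' @param params a [burst_params()].
#' @return data.frame with `channel_id`, `start_s`, `end_s`, `n_spikes`.
#' @export
detect_well_bursts <- function(well, params = burst_params()) {
  stopifnot(inherits(well, "mea_well"))
  res <- lapply(well$channels, function(ch) {
    b <- detect_bursts(channel_spikes(well, ch), params)
    if (nrow(b)) cbind(channel_id = ch, b) else NULL
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    res <- data.frame(channel_id = character(), start_s = numeric(),
                      end_s = numeric(), n_spikes = integer())
  }
  rownames(res) <- NULL
  res
}

#' Active channels of a well
#'
#' A channel is active when its mean firing rate strictly exceeds
#' `active_mfr_hz` (default 0.1 Hz).
#'
#' @param well an [mea_well()].
#' @param params a [burst_params()].
#' @return Character vector of active channel ids.
#' @export
active_channels <- function(well, params = burst_params()) {
  stopifnot(inherits(well, "mea_well"))
  counts <- table(factor(well$spikes$channel_id, levels = well$channels))
  rate <- as.numeric(counts) / well$duration_s
  well$channels[rate > params$active_mfr_hz]
}

#' Detect network bursts in a well
#'
#' A sweep line over the single-channel burst intervals counts how many
#' channels are simultaneously in burst. Every maximal interval where this
#' count strictly exceeds `nb_channel_fraction` times the number of active
#' channels seeds a network burst; the network-burst window is the union of
#' all single-channel bursts intersecting the seed interval, overlapping
#' windows are merged, and the participating channels are those contributing
#' a burst to the final window.
#'
#' @param well an [mea_well()].
#' @param bursts per-channel burst table from [detect_well_bursts()]; if
#'   `NULL` it is computed.
#' @param params a [burst_params()].
#' @return data.frame of class `mea_network_bursts` with `start_s`, `end_s`,
#'   `n_channels`, `n_spikes` and a list column `channels`.
#' @export
detect_network_bursts <- function(well, bursts = NULL,
                                  params = burst_params()) {
  stopifnot(inherits(well, "mea_well"))
  if (is.null(bursts)) bursts <- detect_well_bursts(well, params)
  empty <- data.frame(start_s = numeric(), end_s = numeric(),
                      n_channels = integer(), n_spikes = integer())
  empty$channels <- list()
  class(empty) <- c("mea_network_bursts", "data.frame")

  act <- active_channels(well, params)
  n_active <- length(act)
  if (n_active == 0) {
    warning("no active channels; no network bursts detectable",
            call. = FALSE)
    return(empty)
  }
  if (!nrow(bursts)) return(empty)

  thr <- params$nb_channel_fraction * n_active
  required <- if (abs(thr - round(thr)) < 1e-9) round(thr) + 1L else
    as.integer(ceiling(thr))

  # sweep line: +1 at burst starts, -1 at burst ends (starts first at ties)
  ev_t <- c(bursts$start_s, bursts$end_s)
  ev_d <- c(rep(1L, nrow(bursts)), rep(-1L, nrow(bursts)))
  o <- order(ev_t, -ev_d)
  ev_t <- ev_t[o]; ev_d <- ev_d[o]
  cnt <- cumsum(ev_d)
  above <- cnt >= required
  if (!any(above)) return(empty)
  # maximal seed intervals where the count stays at or above `required`
  runs <- rle(above)
  pos <- cumsum(runs$lengths)
  seed_start <- ev_t[c(0, pos)[which(runs$values)] + 1]
  seed_end <- ev_t[pmin(pos[which(runs$values)] + 1, length(ev_t))]

  # window = union of bursts intersecting the seed interval
  win <- lapply(seq_along(seed_start), function(i) {
    hit <- bursts$start_s <= seed_end[i] & bursts$end_s >= seed_start[i]
    c(min(bursts$start_s[hit]), max(bursts$end_s[hit]))
  })
  win <- do.call(rbind, win)
  win <- win[order(win[, 1]), , drop = FALSE]
  # merge overlapping windows
  ws <- win[1, 1]; we <- win[1, 2]
  if (nrow(win) > 1) {
    for (i in 2:nrow(win)) {
      k <- length(ws)
      if (win[i, 1] <= we[k]) we[k] <- max(we[k], win[i, 2])
      else { ws <- c(ws, win[i, 1]); we <- c(we, win[i, 2]) }
    }
  }
  chans <- lapply(seq_along(ws), function(i) {
    sort(unique(bursts$channel_id[bursts$start_s <= we[i] &
                                    bursts$end_s >= ws[i]]))
  })
  nsp <- vapply(seq_along(ws), function(i) {
    sum(well$spikes$time_s >= ws[i] & well$spikes$time_s <= we[i])
  }, integer(1))
  out <- data.frame(start_s = ws, end_s = we,
                    n_channels = lengths(chans), n_spikes = nsp)
  out$channels <- chans
  rownames(out) <- NULL
  class(out) <- c("mea_network_bursts", "data.frame")
  out
}
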
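#' Raw extracellular trace
#'
#' @param channel_id channel label.
#' @param samples numeric voltage samples (µV); must be finite.
#' @param sampling_rate_hz sampling rate in Hz (default 10 kHz).
#' @return An object of class `raw_trace`.
#' @export
raw_trace <- function(channel_id, samples, sampling_rate_hz = 10000) {
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("'sampling_rate_hz' must be > 0", call. = FALSE)
  }
  if (!is.numeric(samples) || any(!is.finite(samples))) {
    stop("'samples' must be finite numeric", call. = FALSE)
  }
  structure(list(channel_id = as.character(channel_id),
                 samples = as.numeric(samples),
                 sampling_rate_hz = sampling_rate_hz),
            class = "raw_trace")
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("<raw_trace> %s: %d samples @ %g Hz (%.2f s)\n",
              x$channel_id, length(x$samples), x$sampling_rate_hz,
              length(x$samples) / x$sampling_rate_hz))
  invisible(x)
}

#' Band-limiting filter specification
#'
#' The acquisition chain applies a 2nd-order Butterworth high-pass at 100 Hz
#' followed by a 4th-order Butterworth low-pass at 3500 Hz.
#'
#' @param hp_order,hp_cutoff_hz high-pass order and cutoff.
#' @param lp_order,lp_cutoff_hz low-pass order and cutoff.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(hp_order = 2, hp_cutoff_hz = 100,
                        lp_order = 4, lp_cutoff_hz = 3500) {
  if (hp_cutoff_hz <= 0 || lp_cutoff_hz <= hp_cutoff_hz) {
    stop("need 0 < hp_cutoff_hz < lp_cutoff_hz", call. = FALSE)
  }
  if (hp_order < 1 || lp_order < 1) stop("filter orders must be >= 1",
                                         call. = FALSE)
  structure(list(hp_order = hp_order, hp_cutoff_hz = hp_cutoff_hz,
                 lp_order = lp_order, lp_cutoff_hz = lp_cutoff_hz),
            class = "filter_spec")
}

#' Band-limit a raw trace
#'
#' Applies the Butterworth high-pass then low-pass of `spec`, each
#' forward-backward (zero-phase, [signal::filtfilt()]) so spike timestamps
#' are not shifted. The high-pass removes the DC component.
#'
#' @param trace a [raw_trace()].
#' @param spec a [filter_spec()]; cutoffs must be below the Nyquist rate.
#' @return The filtered `raw_trace`, same length and sampling rate.
#' @export
bandlimit <- function(trace, spec = filter_spec()) {
  stopifnot(inherits(trace, "raw_trace"), inherits(spec, "filter_spec"))
  nyq <- trace$sampling_rate_hz / 2
  if (spec$lp_cutoff_hz >= nyq) {
    stop(sprintf("low-pass cutoff %g Hz is not below the Nyquist rate %g Hz",
                 spec$lp_cutoff_hz, nyq), call. = FALSE)
  }
  hp <- signal::butter(spec$hp_order, spec$hp_cutoff_hz / nyq, type = "high")
  lp <- signal::butter(spec$lp_order, spec$lp_cutoff_hz / nyq, type = "low")
  y <- signal::filtfilt(hp, trace$samples)
  y <- signal::filtfilt(lp, y)
  raw_trace(trace$channel_id, y, trace$sampling_rate_hz)
}

#' Robust noise SD of a trace
#'
#' `median(|x|) / 0.6745`, the standard spike-robust estimator: unlike the
#' sample SD it is barely inflated by the spikes themselves.
#'
#' @param x numeric samples or a [raw_trace()].
#' @return Estimated noise SD.
#' @export
noise_sd <- function(x) {
  if (inherits(x, "raw_trace")) x <- x$samples
  stats::median(abs(x)) / 0.6745
}

#' Threshold spike detection
#'
#' Detects spikes on an already band-limited trace at `threshold_sd` times
#' the robust noise SD, both polarities. Each excursion beyond the threshold
#' is reduced to its largest-magnitude sample; events closer than
#' `dead_time_ms` are collapsed to the larger extremum. Spike times are
#' reported at the extremum sample.
#'
#' @param trace a filtered [raw_trace()].
#' @param threshold_sd threshold in noise SDs (default ±4.5).
#' @param dead_time_ms minimum separation between reported spikes (default 1).
#' @param sd_estimate noise SD to use; default the robust estimate
#'   [noise_sd()] of the trace.
#' @return A `spike_train`: list with `channel_id`, sorted `spike_times_s`,
#'   `duration_s`, and the threshold used.
#' @export
detect_spikes <- function(trace, threshold_sd = 4.5, dead_time_ms = 1,
                          sd_estimate = NULL) {
  stopifnot(inherits(trace, "raw_trace"))
  x <- trace$samples
  fs <- trace$sampling_rate_hz
  dur <- length(x) / fs
  if (is.null(sd_estimate)) sd_estimate <- noise_sd(x)
  thr <- threshold_sd * sd_estimate
  out <- function(times) {
    structure(list(channel_id = trace$channel_id,
                   spike_times_s = times, duration_s = dur,
                   threshold = thr),
              class = "spike_train")
  }
  idx <- which(abs(x) > thr)
  if (!length(idx) || thr <= 0) {
    if (thr <= 0 && any(abs(x) > 0)) {
      # zero-noise trace: every nonzero excursion is an event
      idx <- which(abs(x) > 0)
    } else {
      return(out(numeric(0)))
    }
  }
  dead <- max(1L, round(dead_time_ms / 1000 * fs))
  # group suprathreshold samples separated by less than the dead time,
  # keep the largest-magnitude sample of each group
  grp <- cumsum(c(1L, as.integer(diff(idx) > dead)))
  peaks <- vapply(split(idx, grp),
                  function(ii) ii[which.max(abs(x[ii]))], integer(1))
  peaks <- sort(unname(peaks))
  # enforce the dead time between the surviving extrema
  repeat {
    d <- diff(peaks)
    close <- which(d <= dead)
    if (!length(close)) break
    i <- close[1]
    drop <- if (abs(x[peaks[i]]) >= abs(x[peaks[i + 1]])) i + 1L else i
    peaks <- peaks[-drop]
  }
  out((peaks - 1) / fs)
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s: %d spikes in %.2f s (%.3f Hz)\n",
              x$channel_id, length(x$spike_times_s), x$duration_s,
              length(x$spike_times_s) / x$duration_s))
  invisible(x)
}
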
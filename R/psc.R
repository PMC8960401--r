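#' Classify postsynaptic-current events by decay time
#'
#' Spontaneous postsynaptic currents recorded at a fixed holding potential
#' mix fast glutamatergic and slow GABAergic events; a decay-time cutoff
#' separates the two classes. Events with decay time at or below the cutoff
#' are labelled glutamatergic (the boundary goes to the fast class), events
#' above it GABAergic. The decay metric is the fitted single-exponential
#' time constant.
#'
#' @param events data.frame with at least a `decay_ms` column (e.g. from
#'   [simulate_psc_events()]).
#' @param cutoff_ms decay-time cutoff in ms (default 3.8).
#' @return An object of class `mea_psc`: the labelled `events` (column
#'   `assigned_class` added), per-class `counts` and `fractions`, and
#'   `n_dropped` (events with non-positive decay, removed with a message).
#'   With no classifiable events the fractions are `NA`.
#' @export
classify_psc <- function(events, cutoff_ms = 3.8) {
  stopifnot(is.data.frame(events), "decay_ms" %in% names(events))
  if (!is.numeric(cutoff_ms) || length(cutoff_ms) != 1 || cutoff_ms <= 0) {
    stop("'cutoff_ms' must be a single positive number", call. = FALSE)
  }
  bad <- !is.finite(events$decay_ms) | events$decay_ms <= 0
  if (any(bad)) {
    message(sprintf("dropping %d event(s) with non-positive decay time",
                    sum(bad)))
    events <- events[!bad, , drop = FALSE]
  }
  events$assigned_class <- ifelse(events$decay_ms <= cutoff_ms,
                                  "glutamatergic", "GABAergic")
  counts <- c(glutamatergic = sum(events$assigned_class == "glutamatergic"),
              GABAergic = sum(events$assigned_class == "GABAergic"))
  n <- sum(counts)
  fractions <- if (n > 0) counts / n else
    c(glutamatergic = NA_real_, GABAergic = NA_real_)
  structure(list(events = events, counts = counts, fractions = fractions,
                 cutoff_ms = cutoff_ms, n_dropped = sum(bad)),
            class = "mea_psc")
}

#' @export
print.mea_psc <- function(x, ...) {
  cat(sprintf("<mea_psc> cutoff %.1f ms: %d glutamatergic, %d GABAergic",
              x$cutoff_ms, x$counts[["glutamatergic"]],
              x$counts[["GABAergic"]]))
  if (x$n_dropped) cat(sprintf(" (%d dropped)", x$n_dropped))
  cat("\n")
  invisible(x)
}

#' Cell-aggregation assay ratio
#'
#' Particle count after 60 min of incubation relative to the count at time
#' zero (T60/T0). Aggregating cells fuse into fewer, larger particles, so
#' values well below 1 indicate strong adhesion and values near 1 indicate
#' none.
#'
#' @param particles_t0 particle count at time zero (> 0).
#' @param particles_t60 particle count after incubation (>= 0).
#' @return The ratio `particles_t60 / particles_t0`.
#' @export
aggregation_ratio <- function(particles_t0, particles_t60) {
  if (!is.numeric(particles_t0) || length(particles_t0) != 1 ||
      particles_t0 <= 0) {
    stop("'particles_t0' must be a single count > 0", call. = FALSE)
  }
  if (!is.numeric(particles_t60) || length(particles_t60) != 1 ||
      particles_t60 < 0) {
    stop("'particles_t60' must be a single count >= 0", call. = FALSE)
  }
  particles_t60 / particles_t0
}
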
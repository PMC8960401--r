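#' Construct a well recording
#'
#' A well recording bundles all spike trains of one MEA well with its
#' metadata. Spike times are stored in seconds in a long-format table;
#' channels without spikes are kept in `channels` so that silent electrodes
#' still enter per-well averages (e.g. the mean firing rate).
#'
#' @param well_id character scalar identifying the well.
#' @param duration_s recording duration in seconds (> 0).
#' @param spikes data.frame with columns `channel_id`, `time_s`. Times must
#'   lie in `[0, duration_s]`; rows are sorted by channel then time.
#' @param channels character vector of all electrode ids in the well
#'   (defaults to the channels present in `spikes`).
#' @param metadata named list of well-level metadata (e.g. `group`, `div`,
#'   `composition`).
#' @return An object of class `mea_well`.
#' @export
mea_well <- function(well_id, duration_s, spikes,
                     channels = NULL, metadata = list()) {
  stopifnot(is.character(well_id) || is.factor(well_id), length(well_id) == 1)
  if (!is.numeric(duration_s) || length(duration_s) != 1 || !is.finite(duration_s) ||
      duration_s <= 0) {
    stop("'duration_s' must be a single positive number", call. = FALSE)
  }
  if (is.null(spikes)) {
    spikes <- data.frame(channel_id = character(), time_s = numeric())
  }
  if (!all(c("channel_id", "time_s") %in% names(spikes))) {
    stop("'spikes' needs columns 'channel_id' and 'time_s'", call. = FALSE)
  }
  spikes$channel_id <- as.character(spikes$channel_id)
  if (nrow(spikes)) {
    bad <- which(!is.finite(spikes$time_s) | spikes$time_s < 0 |
                   spikes$time_s > duration_s)
    if (length(bad)) {
      stop(sprintf("spike time out of [0, duration] at row %d", bad[1]),
           call. = FALSE)
    }
    spikes <- spikes[order(spikes$channel_id, spikes$time_s), , drop = FALSE]
    rownames(spikes) <- NULL
  }
  if (is.null(channels)) channels <- sort(unique(spikes$channel_id))
  channels <- as.character(channels)
  if (nrow(spikes) && !all(spikes$channel_id %in% channels)) {
    stop("'spikes' contains channels not listed in 'channels'", call. = FALSE)
  }
  structure(
    list(well_id = as.character(well_id), duration_s = as.numeric(duration_s),
         spikes = spikes, channels = channels, metadata = metadata),
    class = "mea_well"
  )
}

#' @export
print.mea_well <- function(x, ...) {
  cat(sprintf("<mea_well> %s: %d channels, %d spikes, %.1f s\n",
              x$well_id, length(x$channels), nrow(x$spikes), x$duration_s))
  if (length(x$metadata)) {
    cat("  metadata:",
        paste(names(x$metadata), unlist(lapply(x$metadata, format)),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Spike times of one channel
#'
#' @param well an `mea_well`.
#' @param channel_id channel label.
#' @return Sorted numeric vector of spike times in seconds.
#' @export
channel_spikes <- function(well, channel_id) {
  stopifnot(inherits(well, "mea_well"))
  well$spikes$time_s[well$spikes$channel_id == channel_id]
}

# derive a reproducible 31-bit sub-seed for a named stream
derive_seed <- function(seed, stream) {
  s <- (as.numeric(seed) %% 2147483647)
  ((s * 48271 + as.numeric(stream) * 16807 + 11) %% 2147483647)
}

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}
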
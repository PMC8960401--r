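#' Per-DIV quality-control summary of one well
#'
#' Builds the one-row summary that [qc_well()] consumes: well mean firing
#' rate, channel counts (total, active at > 0.1 Hz, spiking at all,
#' participating in at least one network burst) and the network-burst rate.
#'
#' @param well an [mea_well()]; its `metadata$div` (if present) is used as
#'   the DIV unless `div` is given.
#' @param div days in vitro of the recording.
#' @param params a [burst_params()].
#' @return One-row data.frame.
#' @export
qc_summary <- function(well, div = NULL, params = burst_params()) {
  stopifnot(inherits(well, "mea_well"))
  if (is.null(div)) div <- well$metadata$div
  if (is.null(div)) stop("no DIV given and none in well metadata",
                         call. = FALSE)
  bursts <- detect_well_bursts(well, params)
  nb <- suppressWarnings(detect_network_bursts(well, bursts, params))
  counts <- table(factor(well$spikes$channel_id, levels = well$channels))
  rate <- as.numeric(counts) / well$duration_s
  data.frame(
    well_id = well$well_id, div = div,
    mfr_hz = mean(rate),
    n_channels = length(well$channels),
    n_active = sum(rate > params$active_mfr_hz),
    n_spiking = sum(rate > 0),
    nbr_per_min = nrow(nb) / well$duration_s * 60,
    n_channels_in_nb = length(unique(unlist(nb$channels))))
}

#' Well inclusion/exclusion rules
#'
#' Evaluates the six exclusion criteria applied before any group analysis;
#' each criterion is evaluated independently and all violated codes are
#' returned:
#' \describe{
#'   \item{INACTIVE}{fewer than three channels with MFR > 0.1 Hz (at any
#'     recorded DIV).}
#'   \item{CONTROL_LOW_MFR}{control wells only: well MFR < 1 Hz.}
#'   \item{FEW_SPIKING_CHANNELS}{spikes detected on < 80\% of the channels.}
#'   \item{NO_NB_AT_DIV28}{no network bursts at DIV 28. If DIV 28 was not
#'     recorded this criterion is not assessable: it is noted, not violated.}
#'   \item{NB_FEW_CHANNELS}{network bursts detected in < 80\% of the
#'     channels (assessed at DIVs where network bursts occur).}
#'   \item{MFR_DECREASING}{well MFR at the last recorded DIV below the
#'     first.}
#' }
#'
#' @param summaries data.frame of per-DIV rows from [qc_summary()] (one
#'   well, one row per DIV).
#' @param role `"treated"` or `"control"`; the 1 Hz MFR floor applies to
#'   control wells only.
#' @return An object of class `mea_qc`: `well_id`, logical `included`,
#'   character `violated` (criterion codes), and `notes`.
#' @export
qc_well <- function(summaries, role = c("treated", "control")) {
  role <- match.arg(role)
  s <- summaries[order(summaries$div), , drop = FALSE]
  violated <- character(0)
  notes <- character(0)

  if (any(s$n_active < 3)) violated <- c(violated, "INACTIVE")
  if (role == "control" && any(s$mfr_hz < 1)) {
    violated <- c(violated, "CONTROL_LOW_MFR")
  }
  if (any(s$n_spiking / s$n_channels < 0.8)) {
    violated <- c(violated, "FEW_SPIKING_CHANNELS")
  }
  if (28 %in% s$div) {
    if (s$nbr_per_min[s$div == 28][1] == 0) {
      violated <- c(violated, "NO_NB_AT_DIV28")
    }
  } else {
    notes <- c(notes, "DIV 28 not recorded; NO_NB_AT_DIV28 not assessable")
  }
  with_nb <- s$nbr_per_min > 0
  if (any(with_nb) &&
      any(s$n_channels_in_nb[with_nb] / s$n_channels[with_nb] < 0.8)) {
    violated <- c(violated, "NB_FEW_CHANNELS")
  }
  if (nrow(s) >= 2 && s$mfr_hz[nrow(s)] < s$mfr_hz[1]) {
    violated <- c(violated, "MFR_DECREASING")
  }
  structure(list(well_id = s$well_id[1], included = !length(violated),
                 violated = violated, notes = notes),
            class = "mea_qc")
}

#' @export
print.mea_qc <- function(x, ...) {
  cat(sprintf("<mea_qc> %s: %s\n", x$well_id,
              if (x$included) "included"
              else paste("excluded:", paste(x$violated, collapse = ", "))))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' QC report over a plate
#'
#' @param summaries data.frame of [qc_summary()] rows for several wells.
#' @param roles named character vector mapping well ids to
#'   `"treated"`/`"control"`; unnamed wells default to `"treated"`.
#' @return data.frame: `well_id`, `included`, `violated` (codes joined by
#'   `;`), `notes`.
#' @export
qc_report <- function(summaries, roles = character(0)) {
  ids <- unique(summaries$well_id)
  rows <- lapply(ids, function(id) {
    role <- if (id %in% names(roles)) roles[[id]] else "treated"
    q <- qc_well(summaries[summaries$well_id == id, , drop = FALSE], role)
    data.frame(well_id = id, included = q$included,
               violated = paste(q$violated, collapse = ";"),
               notes = paste(q$notes, collapse = ";"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
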
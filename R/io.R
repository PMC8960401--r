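#' Write wells to a long-format spike CSV
#'
#' Fixed schema: header `well_id,channel_id,time_s`, UTF-8, `.` decimal,
#' times in seconds. One sidecar-free file can hold a whole plate.
#'
#' @param wells an [mea_well()] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spike_csv <- function(wells, path) {
  if (inherits(wells, "mea_well")) wells <- list(wells)
  tab <- do.call(rbind, lapply(wells, function(w) {
    if (!nrow(w$spikes)) return(NULL)
    data.frame(well_id = w$well_id, w$spikes)
  }))
  if (is.null(tab)) {
    tab <- data.frame(well_id = character(), channel_id = character(),
                      time_s = numeric())
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read wells from a long-format spike CSV
#'
#' @param path CSV file with columns `well_id`, `channel_id`, `time_s`.
#' @param duration_s recording duration; if `NULL` it is inferred per well
#'   as the largest spike time rounded up to a whole second (noted via a
#'   message).
#' @param metadata optional named list of per-well metadata lists, keyed by
#'   well id.
#' @return Named list of [mea_well()] objects, channels sorted by id. Rows
#'   arriving out of order are sorted with a warning; negative spike times
#'   are an error naming the offending row.
#' @export
read_spike_csv <- function(path, duration_s = NULL, metadata = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "channel_id", "time_s")
  if (!all(need %in% names(tab))) {
    stop("spike CSV must have columns well_id, channel_id, time_s",
         call. = FALSE)
  }
  if (!is.numeric(tab$time_s)) {
    bad <- which(is.na(suppressWarnings(as.numeric(tab$time_s))))[1]
    stop(sprintf("malformed time_s at data row %d", bad), call. = FALSE)
  }
  neg <- which(tab$time_s < 0)
  if (length(neg)) {
    stop(sprintf("negative spike time at data row %d", neg[1]),
         call. = FALSE)
  }
  wells <- list()
  for (id in unique(tab$well_id)) {
    sub <- tab[tab$well_id == id, c("channel_id", "time_s")]
    if (!identical(order(sub$channel_id, sub$time_s), seq_len(nrow(sub)))) {
      warning(sprintf("well %s: rows not in channel/time order; sorted", id),
              call. = FALSE)
    }
    dur <- duration_s
    if (is.null(dur)) {
      dur <- max(1, ceiling(max(sub$time_s)))
      message(sprintf("well %s: duration inferred as %g s", id, dur))
    }
    wells[[id]] <- mea_well(id, dur, sub,
                            metadata = if (id %in% names(metadata))
                              metadata[[id]] else list())
  }
  wells
}

#' Write a network spec to a YAML config
#' @param spec a [network_spec()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_spec <- function(spec, path) {
  stopifnot(inherits(spec, "network_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' Read a network spec from a YAML config
#' @param path YAML file written by [write_network_spec()].
#' @return A validated [network_spec()].
#' @export
read_network_spec <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(network_spec, v)
}

#' Pipeline run configuration
#'
#' Bundles and validates everything one end-to-end run needs. All analysis
#' defaults are the standard multiwell settings (30/65/50 ms, 4 spikes, 80%
#' coincidence, 0.1 Hz activity, ±4.5 SD, 100/3500 Hz Butterworth).
#'
#' @param input path to a spike CSV (see [read_spike_csv()]), or `NULL`
#'   when `wells` are passed to [run_pipeline()] directly.
#' @param output_dir directory for all outputs.
#' @param params a [burst_params()].
#' @param filter a [filter_spec()] (recorded in the manifest; applied only
#'   when raw traces are processed upstream).
#' @param bin_width_ms burst-shape bin width.
#' @param qc run the exclusion rules (needs per-well `div` metadata).
#' @param discriminant run canonical discriminant analysis on the nine
#'   parameters (needs per-well `group` metadata).
#' @param roles named vector mapping well ids to `"control"`/`"treated"`.
#' @param duration_s recording duration override for CSV input.
#' @param seed integer seed recorded in the manifest.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL, output_dir = tempfile("mea_run_"),
                       params = burst_params(), filter = filter_spec(),
                       bin_width_ms = 10, qc = TRUE, discriminant = FALSE,
                       roles = character(0), duration_s = NULL, seed = 1L) {
  stopifnot(inherits(params, "burst_params"), inherits(filter, "filter_spec"))
  if (!is.numeric(bin_width_ms) || bin_width_ms <= 0) {
    stop("'bin_width_ms' must be > 0", call. = FALSE)
  }
  structure(list(input = input, output_dir = output_dir, params = params,
                 filter = filter, bin_width_ms = bin_width_ms, qc = qc,
                 discriminant = discriminant, roles = roles,
                 duration_s = duration_s, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline on a plate
#'
#' Loads (or accepts) the wells, detects bursts and network bursts per
#' well, computes the nine-parameter feature table, applies the QC
#' exclusion rules, optionally fits the canonical discriminant analysis on
#' the included wells, and writes everything (feature table, QC report,
#' burst and network-burst tables, manifest) as CSV/JSON into
#' `config$output_dir`. Outputs are deterministic: rerunning the same
#' config yields byte-identical tables.
#'
#' @param config a [run_config()].
#' @param wells optional list of [mea_well()] objects, bypassing
#'   `config$input`.
#' @return Invisibly, a list with `features`, `qc`, `bursts`,
#'   `network_bursts`, `cda` (or `NULL`) and the output file paths.
#' @export
run_pipeline <- function(config, wells = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(wells)) {
    if (is.null(config$input)) stop("no input file and no wells supplied",
                                    call. = FALSE)
    wells <- read_spike_csv(config$input, duration_s = config$duration_s)
  }
  if (inherits(wells, "mea_well")) wells <- list(wells)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- "burst detection"
  res <- tryCatch({
    bursts <- lapply(wells, detect_well_bursts, params = config$params)
    stage <- "network-burst detection"
    nbs <- mapply(function(w, b) {
      suppressWarnings(detect_network_bursts(w, b, config$params))
    }, wells, bursts, SIMPLIFY = FALSE)
    stage <- "feature computation"
    feats <- do.call(rbind, mapply(function(w, b, n) {
      f <- compute_features(w, b, n, config$params)
      for (m in names(w$metadata)) {
        v <- w$metadata[[m]]
        if (length(v) == 1 && is.atomic(v)) f[[m]] <- v
      }
      f
    }, wells, bursts, nbs, SIMPLIFY = FALSE))
    stage <- "quality control"
    qc_tab <- NULL
    if (isTRUE(config$qc)) {
      summ <- do.call(rbind, lapply(wells, function(w) {
        div <- if (!is.null(w$metadata$div)) w$metadata$div else 0
        qc_summary(w, div = div, params = config$params)
      }))
      qc_tab <- qc_report(summ, roles = config$roles)
    }
    stage <- "discriminant analysis"
    cda <- NULL
    if (isTRUE(config$discriminant)) {
      groups <- vapply(wells, function(w)
        as.character(w$metadata$group %||% NA_character_), character(1))
      keep <- if (is.null(qc_tab)) rep(TRUE, length(wells)) else
        qc_tab$included[match(feats$well_id, qc_tab$well_id)]
      nine <- c("mfr_hz", "prs_pct", "burst_rate_per_min",
                "burst_duration_ms", "fr_in_burst_hz", "ibi_s",
                "nbr_per_min", "nbd_ms", "nibi_s")
      cda <- canonical_discriminant(feats[keep, nine, drop = FALSE],
                                    groups[keep])
    }
    list(bursts = bursts, nbs = nbs, feats = feats, qc = qc_tab, cda = cda)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  paths <- list(
    features = file.path(config$output_dir, "features.csv"),
    bursts = file.path(config$output_dir, "bursts.csv"),
    network_bursts = file.path(config$output_dir, "network_bursts.csv"),
    manifest = file.path(config$output_dir, "manifest.json"))
  utils::write.csv(res$feats, paths$features, row.names = FALSE)
  btab <- do.call(rbind, mapply(function(w, b) {
    if (nrow(b)) cbind(well_id = w$well_id, b) else NULL
  }, wells, res$bursts, SIMPLIFY = FALSE))
  if (is.null(btab)) btab <- data.frame(well_id = character(),
                                        channel_id = character(),
                                        start_s = numeric(),
                                        end_s = numeric(),
                                        n_spikes = integer())
  utils::write.csv(btab, paths$bursts, row.names = FALSE)
  ntab <- do.call(rbind, mapply(function(w, n) {
    if (!nrow(n)) return(NULL)
    data.frame(well_id = w$well_id, start_s = n$start_s, end_s = n$end_s,
               n_channels = n$n_channels, n_spikes = n$n_spikes)
  }, wells, res$nbs, SIMPLIFY = FALSE))
  if (is.null(ntab)) ntab <- data.frame(well_id = character(),
                                        start_s = numeric(),
                                        end_s = numeric(),
                                        n_channels = integer(),
                                        n_spikes = integer())
  utils::write.csv(ntab, paths$network_bursts, row.names = FALSE)
  if (!is.null(res$qc)) {
    paths$qc <- file.path(config$output_dir, "qc_report.csv")
    utils::write.csv(res$qc, paths$qc, row.names = FALSE)
  }
  if (!is.null(res$cda)) {
    paths$cda_scores <- file.path(config$output_dir, "cda_scores.csv")
    paths$cda_structure <- file.path(config$output_dir, "cda_structure.csv")
    utils::write.csv(data.frame(group = res$cda$groups, res$cda$scores),
                     paths$cda_scores, row.names = FALSE)
    utils::write.csv(data.frame(variable = rownames(res$cda$structure),
                                res$cda$structure),
                     paths$cda_structure, row.names = FALSE)
  }
  manifest <- list(
    package = "meanet",
    version = as.character(utils::packageVersion("meanet")),
    seed = config$seed,
    parameters = list(burst = unclass(config$params),
                      filter = unclass(config$filter),
                      bin_width_ms = config$bin_width_ms),
    input = if (!is.null(config$input)) {
      list(path = config$input,
           md5 = unname(tools::md5sum(config$input)))
    } else list(path = NA, md5 = NA),
    outputs = lapply(paths, basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(list(features = res$feats, qc = res$qc, bursts = res$bursts,
                   network_bursts = res$nbs, cda = res$cda),
              list(paths = paths)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
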
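#' Nine well-level network activity parameters
#'
#' Computes the feature set used for group comparison and discriminant
#' analysis of E/I networks:
#' \describe{
#'   \item{mfr_hz}{mean firing rate, spikes/s averaged over all electrodes
#'     of the well (silent electrodes included).}
#'   \item{prs_pct}{percentage of random spikes: spikes that belong neither
#'     to a burst on their own channel nor to any network-burst window.}
#'   \item{burst_rate_per_min, burst_duration_ms, fr_in_burst_hz, ibi_s}{
#'     single-channel burst statistics, averaged over channels having at
#'     least one burst (the inter-burst interval needs two).}
#'   \item{nbr_per_min, nbd_ms, nibi_s}{network-burst rate, mean window
#'     duration, and mean network inter-burst interval.}
#' }
#' Inter-burst intervals are measured end-to-next-start. A well without
#' network bursts reports `nbr_per_min = 0` and `NA` (missing, not zero)
#' for `nbd_ms` and `nibi_s`, so group means are not biased toward zero.
#'
#' @param well an [mea_well()].
#' @param bursts per-channel burst table ([detect_well_bursts()]); computed
#'   if `NULL`.
#' @param network_bursts network-burst table ([detect_network_bursts()]);
#'   computed if `NULL`.
#' @param params a [burst_params()].
#' @return One-row data.frame with `well_id`, the nine parameters, and
#'   `n_spikes`.
#' @export
compute_features <- function(well, bursts = NULL, network_bursts = NULL,
                             params = burst_params()) {
  stopifnot(inherits(well, "mea_well"))
  if (is.null(bursts)) bursts <- detect_well_bursts(well, params)
  if (is.null(network_bursts)) {
    network_bursts <- suppressWarnings(
      detect_network_bursts(well, bursts, params))
  }
  dur <- well$duration_s
  feat <- data.frame(well_id = well$well_id, mfr_hz = NA_real_,
                     prs_pct = NA_real_, burst_rate_per_min = NA_real_,
                     burst_duration_ms = NA_real_, fr_in_burst_hz = NA_real_,
                     ibi_s = NA_real_, nbr_per_min = NA_real_,
                     nbd_ms = NA_real_, nibi_s = NA_real_,
                     n_spikes = nrow(well$spikes))
  if (!nrow(well$spikes)) return(feat)

  counts <- table(factor(well$spikes$channel_id, levels = well$channels))
  feat$mfr_hz <- mean(as.numeric(counts) / dur)

  # random spikes: outside own-channel bursts and outside all NB windows
  random <- rep(TRUE, nrow(well$spikes))
  if (nrow(bursts)) {
    for (ch in unique(bursts$channel_id)) {
      i <- which(well$spikes$channel_id == ch)
      b <- bursts[bursts$channel_id == ch, , drop = FALSE]
      inb <- in_any_interval(well$spikes$time_s[i], b$start_s, b$end_s)
      random[i][inb] <- FALSE
    }
  }
  if (nrow(network_bursts)) {
    innb <- in_any_interval(well$spikes$time_s, network_bursts$start_s,
                            network_bursts$end_s)
    random[innb] <- FALSE
  }
  feat$prs_pct <- 100 * sum(random) / nrow(well$spikes)

  if (nrow(bursts)) {
    per_ch <- split(bursts, bursts$channel_id)
    feat$burst_rate_per_min <-
      mean(vapply(per_ch, nrow, integer(1))) / dur * 60
    feat$burst_duration_ms <- mean(vapply(per_ch, function(b)
      mean(b$end_s - b$start_s), numeric(1))) * 1000
    feat$fr_in_burst_hz <- mean(vapply(per_ch, function(b)
      sum(b$n_spikes) / sum(b$end_s - b$start_s), numeric(1)))
    ibis <- vapply(per_ch, function(b) {
      if (nrow(b) < 2) return(NA_real_)
      mean(b$start_s[-1] - b$end_s[-nrow(b)])
    }, numeric(1))
    if (any(!is.na(ibis))) feat$ibi_s <- mean(ibis, na.rm = TRUE)
  }

  nb <- network_bursts
  feat$nbr_per_min <- nrow(nb) / dur * 60
  if (nrow(nb)) {
    feat$nbd_ms <- mean(nb$end_s - nb$start_s) * 1000
    if (nrow(nb) >= 2) {
      feat$nibi_s <- mean(nb$start_s[-1] - nb$end_s[-nrow(nb)])
    }
  }
  feat
}

# TRUE for each t inside any closed interval [start_i, end_i]
in_any_interval <- function(t, start, end) {
  if (!length(start)) return(rep(FALSE, length(t)))
  res <- rep(FALSE, length(t))
  for (i in seq_along(start)) res <- res | (t >= start[i] & t <= end[i])
  res
}

#' Build a feature table for a set of wells
#'
#' Runs burst and network-burst detection on every well and stacks the
#' per-well feature rows, appending scalar metadata fields as columns.
#'
#' @param wells list of [mea_well()] objects.
#' @param params a [burst_params()].
#' @return data.frame, one row per well.
#' @export
feature_table <- function(wells, params = burst_params()) {
  rows <- lapply(wells, function(w) {
    f <- compute_features(w, params = params)
    for (m in names(w$metadata)) {
      v <- w$metadata[[m]]
      if (length(v) == 1 && is.atomic(v)) f[[m]] <- v
    }
    f
  })
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA
    r[all_cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aligned, binned network-burst shapes
#'
#' Each network burst is aligned at its window start and the spikes of all
#' channels inside the window are counted in `bin_width_ms` bins, out to the
#' longest window. The mean profile is the per-bin mean across bursts.
#'
#' @param well an [mea_well()].
#' @param network_bursts table from [detect_network_bursts()].
#' @param bin_width_ms bin width in ms (default 10).
#' @return An object of class `mea_burst_shape`: `bin_width_ms`, the
#'   burst-by-bin count matrix `counts`, `mean_profile`, and `n_bursts`.
#'   With no network bursts, an empty shape flagged by `n_bursts = 0`.
#' @export
burst_shape <- function(well, network_bursts, bin_width_ms = 10) {
  stopifnot(inherits(well, "mea_well"))
  shp <- function(counts) {
    structure(list(bin_width_ms = bin_width_ms, counts = counts,
                   mean_profile = if (nrow(counts)) colMeans(counts)
                   else numeric(0),
                   n_bursts = nrow(counts)),
              class = "mea_burst_shape")
  }
  nb <- network_bursts
  if (is.null(nb) || !nrow(nb)) return(shp(matrix(0, 0, 0)))
  dur_ms <- (nb$end_s - nb$start_s) * 1000
  n_bins <- max(1L, as.integer(ceiling(max(dur_ms) / bin_width_ms - 1e-9)))
  counts <- matrix(0L, nrow(nb), n_bins)
  for (i in seq_len(nrow(nb))) {
    t <- well$spikes$time_s
    t <- t[t >= nb$start_s[i] & t <= nb$end_s[i]]
    rel_ms <- (t - nb$start_s[i]) * 1000
    bin <- pmin(floor(rel_ms / bin_width_ms) + 1L, n_bins)
    tab <- tabulate(bin, nbins = n_bins)
    counts[i, ] <- tab
  }
  shp(counts)
}

#' @export
print.mea_burst_shape <- function(x, ...) {
  cat(sprintf("<mea_burst_shape> %d bursts x %d bins (%g ms bins)\n",
              x$n_bursts, ncol(x$counts), x$bin_width_ms))
  invisible(x)
}

#' Holm–Šidák step-down multiple-comparison procedure
#'
#' Orders the p-values ascending; step i is significant iff
#' `p_(i) <= 1 - (1 - alpha)^(1/(m - i + 1))` and every earlier step was
#' significant. Adjusted p-values are the running maximum of
#' `1 - (1 - p_(i))^(m - i + 1)`.
#'
#' @param p vector of p-values.
#' @param alpha family-wise error rate (default 0.05).
#' @return List with `adjusted` p-values, logical `significant`, and the
#'   per-step `thresholds` (in the original order of `p`).
#' @export
holm_sidak <- function(p, alpha = 0.05) {
  m <- length(p)
  if (!m) return(list(adjusted = numeric(0), significant = logical(0),
                      thresholds = numeric(0)))
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  ord <- order(p)
  k <- m - seq_len(m) + 1
  thr_sorted <- 1 - (1 - alpha)^(1 / k)
  p_sorted <- p[ord]
  adj_sorted <- pmin(1, cummax(1 - (1 - p_sorted)^k))
  sig_sorted <- cumall(!is.na(p_sorted) & p_sorted <= thr_sorted)
  out <- function(v) { r <- v; r[ord] <- v; r }
  list(adjusted = out(adj_sorted), significant = out(sig_sorted),
       thresholds = out(thr_sorted))
}

cumall <- function(x) cumsum(!x) == 0

#' Compare average burst shapes between two groups of wells
#'
#' Runs a per-bin two-sample t-test across wells and applies the
#' Holm–Šidák step-down correction over bins.
#'
#' @param shapes_a,shapes_b either matrices (wells x bins) of per-well mean
#'   profiles, or lists of `mea_burst_shape` objects (their mean profiles
#'   are stacked, right-padded with zeros to a common length).
#' @param alpha family-wise error rate.
#' @param var_equal pooled-variance t-test (default) or Welch.
#' @return data.frame per bin: group means, `t`, `p`, `p_adj`,
#'   `significant`.
#' @export
compare_shapes <- function(shapes_a, shapes_b, alpha = 0.05,
                           var_equal = TRUE) {
  a <- shapes_to_matrix(shapes_a)
  b <- shapes_to_matrix(shapes_b)
  if (!is.null(attr(a, "bin_width")) && !is.null(attr(b, "bin_width")) &&
      attr(a, "bin_width") != attr(b, "bin_width")) {
    stop("bin widths differ between the two groups", call. = FALSE)
  }
  if (nrow(a) < 2 || nrow(b) < 2) {
    stop("need at least two wells per group", call. = FALSE)
  }
  nb <- max(ncol(a), ncol(b))
  pad <- function(m) cbind(m, matrix(0, nrow(m), nb - ncol(m)))
  a <- pad(a); b <- pad(b)
  tt <- vapply(seq_len(nb), function(j) {
    x <- a[, j]; y <- b[, j]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      return(c(t = 0, p = if (mean(x) == mean(y)) 1 else 0))
    }
    r <- stats::t.test(x, y, var.equal = var_equal)
    c(t = unname(r$statistic), p = r$p.value)
  }, c(t = 0, p = 0))
  hs <- holm_sidak(tt["p", ], alpha)
  data.frame(bin = seq_len(nb), mean_a = colMeans(a), mean_b = colMeans(b),
             t = tt["t", ], p = tt["p", ], p_adj = hs$adjusted,
             significant = hs$significant)
}

shapes_to_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.list(x) && all(vapply(x, inherits, logical(1), "mea_burst_shape"))) {
    bw <- unique(vapply(x, `[[`, numeric(1), "bin_width_ms"))
    if (length(bw) != 1) stop("bin widths differ within a group",
                              call. = FALSE)
    profs <- lapply(x, `[[`, "mean_profile")
    nb <- max(lengths(profs))
    m <- do.call(rbind, lapply(profs, function(p) c(p, rep(0, nb - length(p)))))
    attr(m, "bin_width") <- bw
    return(m)
  }
  stop("shapes must be a matrix or a list of mea_burst_shape objects",
       call. = FALSE)
}
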
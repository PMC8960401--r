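# Independent brute-force oracles, written as literal loop transcriptions of
# the analysis rules so they share no code path with the package internals.

# literal detect -> merge -> filter burst detector
brute_bursts <- function(t, max_isi_ms = 30, merge_gap_ms = 65,
                         min_duration_ms = 50, min_spikes = 4) {
  eps <- 1e-9
  cand <- list()
  if (length(t)) {
    cur <- c(t[1])
    for (i in seq_along(t)[-1]) {
      if ((t[i] - t[i - 1]) * 1000 <= max_isi_ms + eps) {
        cur <- c(cur, t[i])
      } else {
        cand[[length(cand) + 1]] <- cur
        cur <- c(t[i])
      }
    }
    cand[[length(cand) + 1]] <- cur
  }
  # transitive merge of candidates < merge_gap_ms apart
  merged <- list()
  for (b in cand) {
    if (length(merged) &&
        (b[1] - max(merged[[length(merged)]])) * 1000 <
        merge_gap_ms - eps) {
      merged[[length(merged)]] <- c(merged[[length(merged)]], b)
    } else {
      merged[[length(merged) + 1]] <- b
    }
  }
  keep <- list()
  for (b in merged) {
    dur_ms <- (max(b) - min(b)) * 1000
    if (dur_ms >= min_duration_ms - eps && length(b) >= min_spikes) {
      keep[[length(keep) + 1]] <- b
    }
  }
  if (!length(keep)) {
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      n_spikes = integer()))
  }
  data.frame(start_s = vapply(keep, min, 0),
             end_s = vapply(keep, max, 0),
             n_spikes = vapply(keep, length, 0L))
}

# literal step-down Holm-Sidak
brute_holm_sidak <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  sig <- logical(m)
  ok <- TRUE
  for (i in seq_len(m)) {
    thr <- 1 - (1 - alpha)^(1 / (m - i + 1))
    ok <- ok && p[ord[i]] <= thr
    sig[ord[i]] <- ok
  }
  sig
}

# dense-eigen canonical discriminant oracle (non-symmetric solve(W) %*% B)
brute_cda <- function(X, groups) {
  X <- as.matrix(X)
  groups <- as.factor(groups)
  grand <- colMeans(X)
  lv <- levels(groups)
  W <- matrix(0, ncol(X), ncol(X))
  B <- matrix(0, ncol(X), ncol(X))
  for (l in lv) {
    Xi <- X[groups == l, , drop = FALSE]
    mi <- colMeans(Xi)
    Ci <- sweep(Xi, 2, mi)
    W <- W + t(Ci) %*% Ci
    B <- B + nrow(Xi) * outer(mi - grand, mi - grand)
  }
  e <- eigen(solve(W) %*% B)
  q <- min(length(lv) - 1, ncol(X))
  lambda <- Re(e$values[seq_len(q)])
  list(eigenvalues = lambda,
       canonical_correlations = sqrt(lambda / (1 + lambda)),
       vectors = Re(e$vectors[, seq_len(q), drop = FALSE]),
       W = W, B = B)
}

# random small spike train on [0, dur]
random_train <- function(n_max = 50, dur = 600) {
  n <- sample.int(n_max, 1)
  # mix coarse and fine spacing so ISIs straddle the 30/65 ms boundaries
  sort(c(runif(ceiling(n / 2), 0, dur),
         cumsum(runif(floor(n / 2), 0.001, 0.1)) +
           runif(1, 0, dur * 0.9)))
}

# deterministic well with identical bursty channels for boundary fixtures
coincident_well <- function(n_bursting, n_active_total, dur = 600,
                            burst_start = 10, n_burst_spikes = 10,
                            isi_s = 0.02) {
  chans <- sprintf("c%02d", seq_len(n_active_total))
  rows <- list()
  for (i in seq_len(n_active_total)) {
    # keep every channel active: > 0.1 Hz background, 1 s spacing
    bg <- seq(100, 100 + 70, by = 1)
    t <- bg
    if (i <= n_bursting) {
      t <- sort(c(t, burst_start + (seq_len(n_burst_spikes) - 1) * isi_s))
    }
    rows[[i]] <- data.frame(channel_id = chans[i], time_s = t)
  }
  mea_well("WB", dur, do.call(rbind, rows), channels = chans)
}
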
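# Shared fixtures and independent oracles. Oracles are deliberately naive:
# they never reuse the package's algorithms.

# Exhaustive-enumeration DTW oracle: walks every monotone path from (1,1) to
# (N,M), accumulating |x_i - y_j| (doubled on diagonal steps), and returns
# the minimum. Exponential; only for N, M <= ~7.
dtw_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  best <- Inf
  walk <- function(i, j, cost) {
    if (cost >= best) return(invisible(NULL))
    if (i == n && j == m) {
      best <<- cost
      return(invisible(NULL))
    }
    if (i < n && j < m) walk(i + 1, j + 1, cost + 2 * abs(x[i + 1] - y[j + 1]))
    if (i < n) walk(i + 1, j, cost + abs(x[i + 1] - y[j]))
    if (j < m) walk(i, j + 1, cost + abs(x[i] - y[j + 1]))
  }
  walk(1, 1, abs(x[1] - y[1]))
  best
}

# Closed-form Kruskal-Wallis oracle with mid-ranks and tie correction.
kw_oracle <- function(groups) {
  pooled <- unlist(groups)
  r <- rank(pooled)
  n <- length(pooled)
  sizes <- lengths(groups)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  rsums <- mapply(function(a, b) sum(r[a:b]), starts, ends)
  h <- 12 / (n * (n + 1)) * sum(rsums^2 / sizes) - 3 * (n + 1)
  ties <- table(pooled)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Normal-equations OLS oracle.
ols_oracle <- function(X, y) as.numeric(solve(t(X) %*% X, t(X) %*% y))

# A quiet simulator configuration: no noise, no spikes, quality metadata
# guaranteed to pass the screen.
quiet_sim_config <- function(...) {
  sim_config(noise = list(cardiac = 0, cardiac_hz = 1.1,
                          respiratory = 0, respiratory_hz = 0.25,
                          lowfreq = 0, lowfreq_hz = 0.1,
                          white = 0, drift = 0, hbr_white = 0),
             spike_rate = 0, ...)
}

# Reduced-rate configuration used for replicated whole-pipeline experiments.
mc_pipeline_config <- function(seed = 1L, ...) {
  pipeline_config(seed = seed,
                  sim = sim_config(n_dyads = 15, sampling_rate = 1, seed = seed, ...),
                  despike_window_s = 3)
}

# Minimal hand-built hemo_series (both subjects), for synchrony-layer tests.
make_hemo <- function(values_by_subject_channel, fs = 7.81,
                      sequence_label = "A", dyad_id = "toy") {
  rows <- purrr::imap_dfr(values_by_subject_channel, function(chans, subj) {
    purrr::imap_dfr(chans, function(v, ch) {
      tibble::tibble(subject = subj, channel = as.integer(ch),
                     sample_index = seq_along(v) - 1L, hbo = v, hbr = -v / 3)
    })
  })
  structure(list(dyad_id = dyad_id, sequence_label = sequence_label,
                 sampling_rate = fs, hemo = rows,
                 retained = dplyr::distinct(rows, subject, channel),
                 exclusions = tibble::tibble(), markers = NULL,
                 delta_sat = 0.5, kappa = NA_real_),
            class = "hemo_series")
}
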
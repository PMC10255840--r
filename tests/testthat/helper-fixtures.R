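# Small shared fixtures: reduced radar profiles and reference
# implementations used as independent oracles.

# tiny profile for fast unit tests: 1.28 s record, 32 range bins
tiny_config <- function(n_frames = 25L) {
  desk_radar_config(n_frames = n_frames, samples_per_chirp = 32L)
}

# brute-force Hampel reference: explicit loops and stats::median only
hampel_reference <- function(x, K, nth) {
  n <- length(x)
  y <- numeric(n)
  for (k in seq_len(n)) {
    lo <- max(1L, k - K)
    hi <- min(n, k + K)
    w <- x[lo:hi]
    m <- median(w)
    s <- 1.4826 * median(abs(w - m))
    y[k] <- if (abs(x[k] - m) > nth * s) m else x[k]
  }
  y
}

# reference metrics from a confusion matrix, written independently of
# report_from_confusion
metrics_by_hand <- function(conf) {
  list(accuracy = sum(diag(conf)) / sum(conf),
       tpr = diag(conf) / rowSums(conf),
       precision = diag(conf) / colSums(conf))
}

# quick constant-velocity cube
linear_cube <- function(d0, rate, config, noise = NULL, seed = 1L) {
  tr <- constant_rate_trajectory(d0, rate,
                                 duration = record_duration(config) + 0.01)
  synthesize_cube(tr, config, noise, seed = seed)
}
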
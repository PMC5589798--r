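# Shared fixtures, all generated in code.

# A burst-count histogram exactly proportional to a zero-truncated
# Binomial(n, p), scaled to N_total complexes (non-integer counts allowed:
# the chi-square fit works on frequencies).
exact_truncated_histogram <- function(n, p, N_total = 500) {
  counts <- N_total * dbinom(seq_len(n), n, p)
  burst_histogram(counts)
}

# Small field of well-separated complexes on a jittered grid, so every
# complex maps to exactly one selectable cluster.
grid_field <- function(n_complex, tagged = 5L, subunits = 5L,
                       spacing_nm = 1000, seed = 1) {
  set.seed(seed)
  side <- ceiling(sqrt(n_complex))
  gx <- (rep(seq_len(side), side)[seq_len(n_complex)] - 0.5) * spacing_nm
  gy <- (rep(seq_len(side), each = side)[seq_len(n_complex)] - 0.5) * spacing_nm
  fld <- simulate_complex_field(side * spacing_nm / 1000, side * spacing_nm / 1000,
                                density_um2 = 0, subunits_per_complex = subunits,
                                tagged_per_complex = tagged, seed = seed)
  fld$complexes <- data.frame(
    complex_id = seq_len(n_complex),
    x_nm = gx + runif(n_complex, -50, 50),
    y_nm = gy + runif(n_complex, -50, 50),
    n_tagged = rep.int(as.integer(tagged), n_complex),
    region = "extrasynaptic", roi = NA_integer_
  )
  fld
}

# Independent brute-force burst counter: number of inter-detection gaps
# exceeding tau, plus one.
brute_burst_count <- function(frames, tau) {
  if (length(frames) == 0L) return(0L)
  f <- sort(frames)
  1L + sum(diff(f) > tau)
}

# Independent O(n^2) MSD: double loop over all position pairs.
brute_msd <- function(traj, frame_rate_hz, max_lag) {
  o <- order(traj$frame)
  fr <- traj$frame[o]; x <- traj$x_nm[o] / 1000; y <- traj$y_nm[o] / 1000
  n <- length(fr)
  acc <- numeric(max_lag); cnt <- integer(max_lag)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dj <- fr[j] - fr[i]
    if (dj <= max_lag) {
      acc[dj] <- acc[dj] + (x[j] - x[i])^2 + (y[j] - y[i])^2
      cnt[dj] <- cnt[dj] + 1L
    }
  }
  lag <- which(cnt > 0)
  data.frame(lag_frames = lag, tau_s = lag / frame_rate_hz,
             msd_um2 = acc[lag] / cnt[lag], n_pairs = cnt[lag])
}
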
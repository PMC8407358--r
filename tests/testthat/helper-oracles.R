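# Independent brute-force oracles and small fixture builders used across tests.

# naive per-window RMS: explicit loop, no cumulative sums
oracle_rms <- function(x, fs, window = 0.4, hop = 0.1) {
  wlen <- round(window * fs)
  hlen <- round(hop * fs)
  starts <- seq.int(1L, length(x) - wlen + 1L, by = hlen)
  vapply(starts, function(s) sqrt(mean(x[s:(s + wlen - 1L)]^2)), numeric(1L))
}

# brute-force burst detection for one channel: per-window RMS by direct loop,
# explicit state machine over windows, midpoint split of overlapping spans
oracle_detect_channel <- function(x, fs, window = 0.4, hop = 0.1, k = 1.5,
                                  min_duration = 0.5) {
  vals <- oracle_rms(x, fs, window, hop)
  thr <- k * sd(vals)
  t_start <- (seq_along(vals) - 1L) * hop
  onsets <- offsets <- numeric(0)
  run_start <- NA_integer_
  for (i in seq_along(vals)) {
    if (vals[i] > thr) {
      if (is.na(run_start)) run_start <- i
    } else if (!is.na(run_start)) {
      dur <- (i - 1L - run_start) * hop + window
      if (dur >= min_duration) {
        onsets <- c(onsets, t_start[run_start])
        offsets <- c(offsets, t_start[i - 1L] + window)
      }
      run_start <- NA_integer_
    }
  }
  if (!is.na(run_start)) {
    i <- length(vals) + 1L
    dur <- (i - 1L - run_start) * hop + window
    if (dur >= min_duration) {
      onsets <- c(onsets, t_start[run_start])
      offsets <- c(offsets, t_start[i - 1L] + window)
    }
  }
  if (length(onsets) > 1L) {
    for (j in seq_len(length(onsets) - 1L)) {
      if (offsets[j] > onsets[j + 1L]) {
        mid <- (offsets[j] + onsets[j + 1L]) / 2
        offsets[j] <- mid
        onsets[j + 1L] <- mid
      }
    }
  }
  data.frame(onset_s = onsets, offset_s = offsets)
}

# recording with a single planted carrier burst in Gaussian noise
make_burst_recording <- function(fs = 250, duration = 60, onset = 30,
                                 burst_dur = 1.5, carrier = 10, amp = 60,
                                 noise_sd = 5, channel = "C4", seed = 42) {
  set.seed(seed)
  n <- duration * fs
  x <- rnorm(n, sd = noise_sd)
  idx <- (round(onset * fs) + 1L):round((onset + burst_dur) * fs)
  tt <- (idx - 1) / fs
  x[idx] <- x[idx] + amp * sin(2 * pi * carrier * tt)
  eeg_recording(matrix(x, nrow = 1), channel, fs)
}

# vectorised draws of Pearson r (and p) for bivariate-normal samples
simulate_cor_pvals <- function(n, rho, reps) {
  x <- matrix(rnorm(n * reps), nrow = n)
  y <- rho * x + sqrt(1 - rho^2) * matrix(rnorm(n * reps), nrow = n)
  mx <- colMeans(x); my <- colMeans(y)
  r <- (colMeans(x * y) - mx * my) /
    sqrt((colMeans(x^2) - mx^2) * (colMeans(y^2) - my^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tt), df = n - 2))
}
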
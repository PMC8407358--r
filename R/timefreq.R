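#' Default log-spaced frequency grid for burst time-frequency maps
#'
#' @param n number of frequencies (default 60).
#' @param low,high grid limits in Hz (defaults 0.2 and 40).
#' @return strictly increasing numeric vector of frequencies.
#' @export
tfr_frequencies <- function(n = 60, low = 0.2, high = 40) {
  exp(seq(log(low), log(high), length.out = n))
}

#' Default cycles schedule for the Morlet wavelet family
#'
#' Cycles increase linearly with frequency from 3 at 0.2 Hz to 135 at 40 Hz.
#' The linear-in-frequency schedule keeps the wavelets' spectral bandwidth
#' (roughly `f / cycles`) comparable to the spacing of the log-spaced grid
#' across the whole band, so power at frequencies falling between grid points
#' is still registered at the nearest grid frequency; a schedule growing
#' linearly in log-frequency would make mid-band wavelets far narrower than
#' the grid spacing and blind to off-grid activity.
#'
#' @param frequencies frequencies in Hz.
#' @return cycles per frequency (non-decreasing).
#' @export
tfr_cycles <- function(frequencies) {
  3 + (135 - 3) * (frequencies - 0.2) / (40 - 0.2)
}

#' Morlet wavelet instantaneous power of one channel
#'
#' Convolves the channel with a family of complex Morlet wavelets (Gaussian
#' envelope, `cycles[i]` cycles at `frequencies[i]`) via FFT. Wavelets are
#' gain-normalised so that a pure sinusoid of amplitude A at a grid frequency
#' yields squared magnitude A^2 there; instantaneous band power in uV^2
#' (mean-square convention, A^2/2 for a sinusoid) is therefore
#' `power / 2`.
#'
#' @param rec an [eeg_recording()].
#' @param channel channel label.
#' @param frequencies analysis frequencies in Hz, strictly increasing and
#'   below Nyquist (default [tfr_frequencies()]).
#' @param cycles wavelet cycles per frequency, positive and non-decreasing
#'   (default [tfr_cycles()]).
#' @return list with `power` (frequencies x samples matrix of squared wavelet
#'   magnitude), `frequencies`, `times` (seconds).
#' @export
morlet_power <- function(rec, channel, frequencies = tfr_frequencies(),
                         cycles = tfr_cycles(frequencies)) {
  stopifnot(inherits(rec, "eeg_recording"))
  i <- match(channel, rec$channel_labels)
  if (is.na(i)) stop("unknown channel: ", channel)
  fs <- rec$sampling_rate
  if (any(frequencies >= fs / 2)) stop("frequency at or above Nyquist")
  if (any(frequencies <= 0)) stop("frequencies must be positive")
  if (is.unsorted(frequencies, strictly = TRUE))
    stop("frequencies must be strictly increasing")
  if (any(cycles <= 0) || is.unsorted(cycles))
    stop("cycles must be positive and non-decreasing with frequency")

  x <- rec$signal[i, ]
  n <- length(x)
  half_max <- ceiling(4 * max(cycles / (2 * pi * frequencies)) * fs)
  nfft <- stats::nextn(n + 2L * half_max + 1L, 2L)
  fx <- stats::fft(c(x, numeric(nfft - n)))

  pw <- matrix(0, nrow = length(frequencies), ncol = n)
  for (k in seq_along(frequencies)) {
    f <- frequencies[k]
    sd_t <- cycles[k] / (2 * pi * f)
    half <- ceiling(4 * sd_t * fs)
    tt <- (-half:half) / fs
    env <- exp(-tt^2 / (2 * sd_t^2))
    kern <- (2 / sum(env)) * env * exp(2i * pi * f * tt)
    fk <- stats::fft(c(kern, complex(real = numeric(nfft - length(kern)))))
    conv <- stats::fft(fx * fk, inverse = TRUE) / nfft
    # centre of the kernel aligns sample j of x with conv element j + half
    pw[k, ] <- Mod(conv[(half + 1L):(half + n)])^2
  }
  list(power = pw, frequencies = frequencies, times = (seq_len(n) - 1L) / fs)
}

#' Grand-average burst time-frequency map relative to a pre-onset baseline
#'
#' For every eligible burst at `channel`, wavelet power over the epoch
#' \[-baseline, +post\] seconds around onset is converted to dB relative to
#' that burst's own baseline: the per-frequency mean of dB power over the
#' `baseline` seconds preceding onset is subtracted, so each burst's baseline
#' rows average exactly 0 dB. Maps are then averaged across bursts. Bursts
#' whose epoch extends past the recording edges or overlaps artifact-masked
#' samples are skipped (not zero-padded) and counted.
#'
#' Because baseline correction is a subtraction in dB, the map is invariant
#' to any overall gain applied to the recording.
#'
#' @param rec an [eeg_recording()].
#' @param events burst events data.frame (`channel`, `onset_s`, `offset_s`).
#' @param channel channel to characterise.
#' @param baseline pre-onset baseline length in seconds (default 11).
#' @param post seconds after onset included in the map (default 4).
#' @param frequencies,cycles wavelet family (see [morlet_power()]).
#' @return object of class `tfr_map`: list with `power_db` (frequencies x
#'   times), `frequencies`, `times` (s relative to onset),
#'   `n_bursts_averaged`, `n_skipped`, `channel`.
#' @export
burst_tfr <- function(rec, events, channel, baseline = 11, post = 4,
                      frequencies = tfr_frequencies(),
                      cycles = tfr_cycles(frequencies)) {
  stopifnot(inherits(rec, "eeg_recording"))
  ev <- events[events$channel == channel, , drop = FALSE]
  if (!nrow(ev)) stop("no events at channel ", channel)
  fs <- rec$sampling_rate
  n <- ncol(rec$signal)
  mp <- morlet_power(rec, channel, frequencies, cycles)

  nb <- round(baseline * fs)
  np <- round(post * fs)
  rel_t <- ((-nb):(np - 1L)) / fs
  base_cols <- seq_len(nb)
  acc <- NULL
  used <- 0L
  skipped <- 0L
  for (k in seq_len(nrow(ev))) {
    c0 <- floor(ev$onset_s[k] * fs) + 1L
    cols <- (c0 - nb):(c0 + np - 1L)
    if (cols[1L] < 1L || cols[length(cols)] > n ||
        any(rec$artifact_mask[cols])) {
      skipped <- skipped + 1L
      next
    }
    db <- 10 * log10(pmax(mp$power[, cols, drop = FALSE], .Machine$double.xmin))
    db <- db - rowMeans(db[, base_cols, drop = FALSE])
    acc <- if (is.null(acc)) db else acc + db
    used <- used + 1L
  }
  if (used == 0L) stop("no eligible events (all lacked a clean ", baseline,
                       "-s baseline or a full epoch)")
  if (skipped > 0L)
    warning(skipped, " event(s) skipped: incomplete or masked epoch")
  structure(list(power_db = acc / used, frequencies = frequencies,
                 times = rel_t, n_bursts_averaged = used,
                 n_skipped = skipped, channel = channel),
            class = "tfr_map")
}

#' @export
print.tfr_map <- function(x, ...) {
  cat(sprintf("<tfr_map> channel %s: %d frequencies (%.2g-%.2g Hz) x %d times (%.1f to %.1f s), %d bursts averaged\n",
              x$channel, length(x$frequencies), min(x$frequencies),
              max(x$frequencies), length(x$times), min(x$times), max(x$times),
              x$n_bursts_averaged))
  invisible(x)
}
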
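#' Bin burst power into a regular time series
#'
#' Builds the regular series the sleep-cycle spectral analysis consumes: the
#' mean normalised power of bursts whose onset falls in each `bin_width`-second
#' bin. Empty interior bins are filled by linear interpolation (edge bins by
#' nearest value) and flagged.
#'
#' @param events burst events with `channel`, `onset_s` and
#'   `normalised_power_uv2` columns (ground-truth tables from the simulator
#'   work directly; artifact rows are ignored).
#' @param bin_width bin width in seconds (default 60; resolves periods of
#'   0.25 h and longer comfortably).
#' @param channel channel whose bursts form the series.
#' @param duration_s total series span in seconds (default: last burst offset).
#' @param clean_seconds artifact-free duration in seconds used for the
#'   reliability rule downstream (default `duration_s`).
#' @return object of class `burst_power_series`: list with `times_h` (bin
#'   centres, hours), `values` (uV^2), `interpolated` (logical),
#'   `bin_width`, `channel`, `clean_duration_h`.
#' @export
build_power_series <- function(events, bin_width = 60, channel,
                               duration_s = NULL, clean_seconds = NULL) {
  if ("kind" %in% names(events)) events <- events[events$kind == "burst", ]
  ev <- events[events$channel == channel, , drop = FALSE]
  if (nrow(ev) < 2L) stop("need at least 2 bursts on channel ", channel)
  if (is.null(duration_s)) duration_s <- max(ev$offset_s)
  if (is.null(clean_seconds)) clean_seconds <- duration_s
  n_bins <- max(1L, floor(duration_s / bin_width))
  bin <- pmin(n_bins, floor(ev$onset_s / bin_width) + 1L)
  vals <- rep(NA_real_, n_bins)
  agg <- tapply(ev$normalised_power_uv2, bin, mean)
  vals[as.integer(names(agg))] <- agg
  interpolated <- is.na(vals)
  if (any(interpolated)) {
    if (all(interpolated)) stop("no bursts fell inside the series span")
    filled <- stats::approx(which(!interpolated), vals[!interpolated],
                            xout = seq_len(n_bins), rule = 2)$y
    vals[interpolated] <- filled[interpolated]
  }
  structure(list(times_h = ((seq_len(n_bins) - 0.5) * bin_width) / 3600,
                 values = vals, interpolated = interpolated,
                 bin_width = bin_width, channel = channel,
                 clean_duration_h = clean_seconds / 3600),
            class = "burst_power_series")
}

#' Estimate the sleep-cycle period of burst power
#'
#' Mean-removes the binned burst-power series and takes the magnitude of its
#' discrete Fourier transform (no taper). The highest-magnitude frequency bin
#' whose period is below `max_period` hours (and above twice the bin width)
#' is returned as the sleep-cycle estimate. The estimate is flagged
#' unreliable when the artifact-free recording is shorter than
#' `min_reliable_duration` hours, since for short recordings the identified
#' peak is driven almost entirely by recording length.
#'
#' @param series a [build_power_series()] result.
#' @param max_period longest period accepted as a sleep cycle, hours
#'   (default 3.5).
#' @param min_reliable_duration minimum artifact-free duration for a reliable
#'   estimate, hours (default 4.5).
#' @return object of class `sleep_cycle_estimate`: list with `period_h`
#'   (`NA` when the series has no modulation), `amplitude` (spectral
#'   magnitude, arbitrary units), `reliable`, `channel`.
#' @export
estimate_cycle <- function(series, max_period = 3.5,
                           min_reliable_duration = 4.5) {
  stopifnot(inherits(series, "burst_power_series"))
  v <- series$values
  n <- length(v)
  if (n < 2L) stop("series shorter than 2 bins")
  v <- v - mean(v)
  mag <- Mod(stats::fft(v))[seq_len(floor(n / 2)) + 1L]  # k = 1 .. n/2
  period_s <- n * series$bin_width / seq_along(mag)
  ok <- period_s / 3600 < max_period & period_s > 2 * series$bin_width
  period_h <- NA_real_
  amplitude <- NA_real_
  if (any(ok) && max(mag[ok]) > 1e-10 * max(mag, 1e-300)) {
    k <- which(ok)[which.max(mag[ok])]
    period_h <- period_s[k] / 3600
    amplitude <- mag[k]
  }
  reliable <- !is.na(period_h) &&
    series$clean_duration_h >= min_reliable_duration
  structure(list(period_h = period_h, amplitude = amplitude,
                 reliable = reliable, channel = series$channel),
            class = "sleep_cycle_estimate")
}

#' @export
print.sleep_cycle_estimate <- function(x, ...) {
  cat(sprintf("<sleep_cycle_estimate> channel %s: period %.2f h (amplitude %.3g), %s\n",
              x$channel, x$period_h, x$amplitude,
              if (isTRUE(x$reliable)) "reliable" else "UNRELIABLE"))
  invisible(x)
}

#' Check that cycle estimates are independent of recording length and masking
#'
#' Correlates estimated period and amplitude against recording duration and
#' the fraction of EEG masked as artifact, across recordings. A dependence at
#' p < .05 is flagged: reliable sleep-cycle estimates should not be
#' predictable from how much data went into them.
#'
#' @param periods_h estimated periods, hours (one per recording).
#' @param amplitudes_h estimated spectral amplitudes (one per recording).
#' @param durations_h recording durations, hours.
#' @param masked_fractions fraction of each recording masked as artifact.
#' @return data.frame with columns `measure`, `against`, `r`, `p`, `flagged`.
#' @export
cycle_reliability_check <- function(periods_h, amplitudes_h, durations_h,
                                    masked_fractions) {
  n <- length(periods_h)
  if (n < 3L) stop("need at least 3 recordings")
  stopifnot(length(amplitudes_h) == n, length(durations_h) == n,
            length(masked_fractions) == n)
  pairs <- expand.grid(measure = c("period", "amplitude"),
                       against = c("duration", "masked_fraction"),
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    x <- if (pairs$measure[k] == "period") periods_h else amplitudes_h
    y <- if (pairs$against[k] == "duration") durations_h else masked_fractions
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(data.frame(pairs[k, ], r = NA_real_, p = NA_real_,
                        flagged = FALSE))
    ct <- stats::cor.test(x[ok], y[ok])
    data.frame(pairs[k, ], r = unname(ct$estimate), p = ct$p.value,
               flagged = ct$p.value < 0.05)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Correlation between burst power and time since the last burst
#'
#' Per channel, the Pearson correlation between each burst's normalised power
#' and the silent gap preceding it (onset minus previous burst's offset; the
#' first burst at a channel is excluded). Pairs whose gap overlaps an
#' artifact-masked interval are excluded when `mask` is given. The mean of
#' per-channel coefficients is reported, the convention used when this
#' coupling is summarised per infant. A positive mean indicates sleep-cycle
#' phase coupling: longer silences precede more powerful bursts.
#'
#' @param events burst events with `channel`, `onset_s`, `offset_s`,
#'   `normalised_power_uv2` (artifact rows ignored).
#' @param mask optional data.frame of masked intervals (`onset_s`,
#'   `offset_s`), e.g. from [mask_intervals()].
#' @param interval `"gap"` (default; onset minus previous offset) or
#'   `"onset"` (onset-to-onset interval).
#' @param min_events minimum bursts per included channel (default 3).
#' @return list with `per_channel_r` (named), `mean_r`, `n_bursts`.
#' @export
interval_power_correlation <- function(events, mask = NULL,
                                       interval = c("gap", "onset"),
                                       min_events = 3L) {
  interval <- match.arg(interval)
  if ("kind" %in% names(events)) events <- events[events$kind == "burst", ]
  chans <- unique(events$channel)
  rs <- c()
  n_used <- 0L
  for (ch in chans) {
    ev <- events[events$channel == ch, , drop = FALSE]
    ev <- ev[order(ev$onset_s), , drop = FALSE]
    if (nrow(ev) < min_events) next
    i <- seq(2L, nrow(ev))
    gap <- if (interval == "gap") ev$onset_s[i] - ev$offset_s[i - 1L]
           else ev$onset_s[i] - ev$onset_s[i - 1L]
    pw <- ev$normalised_power_uv2[i]
    keep <- rep(TRUE, length(i))
    if (!is.null(mask) && nrow(mask)) {
      g0 <- ev$offset_s[i - 1L]; g1 <- ev$onset_s[i]
      for (m in seq_len(nrow(mask)))
        keep <- keep & !(g0 < mask$offset_s[m] & g1 > mask$onset_s[m])
    }
    if (sum(keep) < 2L || stats::sd(gap[keep]) == 0 ||
        stats::sd(pw[keep]) == 0) next
    rs[ch] <- stats::cor(gap[keep], pw[keep])
    n_used <- n_used + sum(keep) + 1L
  }
  if (!length(rs)) stop("no channel with at least ", min_events, " bursts")
  list(per_channel_r = rs, mean_r = mean(rs), n_bursts = n_used)
}
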
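#' Detection configuration for cortical bursts
#'
#' Parameters of the RMS sliding-window burst detector: band-pass the signal
#' to 8-30 Hz, compute RMS over sliding 400-ms windows, and call a burst any
#' maximal run of windows strictly above `threshold_multiplier` times the
#' standard deviation of the channel's RMS series lasting at least
#' `min_duration` seconds.
#'
#' @param band_low,band_high band edges in Hz (defaults 8 and 30).
#' @param window RMS window length in seconds (default 0.4).
#' @param hop window hop in seconds (default 0.1, i.e. 75% overlap; resolves
#'   the 0.5-s duration criterion to about 0.1 s).
#' @param threshold_multiplier multiple of the per-channel RMS standard
#'   deviation used as detection threshold (default 1.5).
#' @param min_duration minimum burst duration in seconds (default 0.5).
#' @return list of class `detection_config`.
#' @export
detection_config <- function(band_low = 8, band_high = 30, window = 0.4,
                             hop = 0.1, threshold_multiplier = 1.5,
                             min_duration = 0.5) {
  if (band_low <= 0 || band_low >= band_high)
    stop("need 0 < band_low < band_high")
  if (window <= 0 || hop <= 0 || window < hop)
    stop("need window >= hop > 0")
  if (threshold_multiplier <= 0) stop("threshold_multiplier must be > 0")
  structure(list(band_low = band_low, band_high = band_high, window = window,
                 hop = hop, threshold_multiplier = threshold_multiplier,
                 min_duration = min_duration),
            class = "detection_config")
}

#' Zero-phase band-pass filter of a recording
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (zero-phase, so burst timing is preserved). The artifact mask is carried
#' through unchanged.
#'
#' @param rec an [eeg_recording()].
#' @param low,high band edges in Hz; must satisfy `0 < low < high < Nyquist`.
#' @param order Butterworth design order (default 4).
#' @return band-passed [eeg_recording()].
#' @export
bandpass_recording <- function(rec, low = 8, high = 30, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sampling_rate / 2
  if (low <= 0 || high <= low || high >= nyq)
    stop("band must satisfy 0 < low < high < Nyquist")
  bp <- signal::butter(order, c(low, high) / nyq, type = "pass")
  for (i in seq_len(nrow(rec$signal)))
    rec$signal[i, ] <- signal::filtfilt(bp, rec$signal[i, ])
  rec
}

#' Sliding-window RMS series per channel
#'
#' RMS amplitude of each channel over sliding windows (default 400 ms at
#' 100-ms hops). Windows that overlap any artifact-masked sample are flagged
#' and excluded from detection statistics.
#'
#' @param rec an [eeg_recording()] (normally already band-passed).
#' @param window window length in seconds.
#' @param hop hop between window starts in seconds.
#' @return object of class `rms_series`: list with `values` (channels x
#'   windows matrix, uV), `flagged` (logical per window), `t_start` (window
#'   start times, s), `window`, `hop`, `channel_labels`.
#' @export
rms_series <- function(rec, window = 0.4, hop = 0.1) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (window <= 0 || hop <= 0 || window < hop) stop("need window >= hop > 0")
  fs <- rec$sampling_rate
  wlen <- round(window * fs)
  hlen <- max(1L, round(hop * fs))
  n <- ncol(rec$signal)
  if (wlen > n) stop("window longer than recording")
  starts <- seq.int(1L, n - wlen + 1L, by = hlen)
  nch <- nrow(rec$signal)
  vals <- matrix(0, nrow = nch, ncol = length(starts),
                 dimnames = list(rec$channel_labels, NULL))
  for (i in seq_len(nch)) {
    cs <- c(0, cumsum(rec$signal[i, ]^2))
    vals[i, ] <- sqrt((cs[starts + wlen] - cs[starts]) / wlen)
  }
  cm <- c(0L, cumsum(rec$artifact_mask))
  flagged <- (cm[starts + wlen] - cm[starts]) > 0L
  structure(list(values = vals, flagged = flagged,
                 t_start = (starts - 1L) / fs,
                 window = window, hop = hop,
                 channel_labels = rec$channel_labels),
            class = "rms_series")
}

#' Detect cortical bursts from an RMS series
#'
#' Per channel, the detection threshold is `threshold_multiplier` times the
#' standard deviation of that channel's unflagged RMS values over the whole
#' recording. Maximal runs of consecutive windows strictly above threshold
#' lasting at least `min_duration` seconds become burst events; runs that
#' contain or touch an artifact-flagged window are discarded. Event onset and
#' offset span the first window's start to the last window's end; where the
#' 400-ms window span of adjacent events would overlap (possible with
#' overlapping windows), the boundary is split at the midpoint so events at a
#' channel never overlap.
#'
#' A channel whose unflagged RMS has zero standard deviation (e.g. a constant
#' signal) has no amplitude structure to threshold and yields no events.
#'
#' @param rms an [rms_series()].
#' @param cfg a [detection_config()].
#' @return data.frame with columns `channel`, `onset_s`, `offset_s`,
#'   `duration_s`, ordered by channel then onset.
#' @export
detect_bursts <- function(rms, cfg = detection_config()) {
  stopifnot(inherits(rms, "rms_series"), inherits(cfg, "detection_config"))
  out <- list()
  for (i in seq_len(nrow(rms$values))) {
    ch <- rms$channel_labels[i]
    ok <- !rms$flagged
    if (!any(ok)) {
      warning("all windows masked on channel ", ch, "; no events returned")
      next
    }
    thr <- cfg$threshold_multiplier * stats::sd(rms$values[i, ok])
    if (!is.finite(thr) || thr == 0) next
    above <- rms$values[i, ] > thr
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts_run <- ends - r$lengths + 1L
    onset <- offset <- numeric(0)
    nw <- length(above)
    for (k in which(r$values)) {
      a <- starts_run[k]; b <- ends[k]
      dur <- (b - a) * rms$hop + rms$window
      if (dur < cfg$min_duration) next
      touches <- any(rms$flagged[a:b]) ||
        (a > 1L && rms$flagged[a - 1L]) ||
        (b < nw && rms$flagged[b + 1L])
      if (touches) next
      onset <- c(onset, rms$t_start[a])
      offset <- c(offset, rms$t_start[b] + rms$window)
    }
    if (length(onset) > 1L) {
      # split any overlap between adjacent events at the midpoint
      for (k in seq_len(length(onset) - 1L)) {
        if (offset[k] > onset[k + 1L]) {
          mid <- (offset[k] + onset[k + 1L]) / 2
          offset[k] <- mid
          onset[k + 1L] <- mid
        }
      }
    }
    if (length(onset))
      out[[ch]] <- data.frame(channel = ch, onset_s = onset,
                              offset_s = offset,
                              duration_s = offset - onset)
  }
  if (!length(out))
    return(data.frame(channel = character(0), onset_s = numeric(0),
                      offset_s = numeric(0), duration_s = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Duration-normalised band power of each burst
#'
#' Band-passes the recording to `band` and annotates each event with its
#' duration-normalised power: the integral of instantaneous power (squared
#' band-passed amplitude) over the burst divided by burst duration, i.e. the
#' mean squared band-passed amplitude, in uV^2. For a pure sinusoid of
#' amplitude A this is A^2/2.
#'
#' @param rec the (unfiltered) [eeg_recording()] the events were detected in.
#' @param events data.frame as returned by [detect_bursts()].
#' @param band numeric length-2, band edges in Hz (default `c(8, 30)`).
#' @return `events` with an added `normalised_power_uv2` column.
#' @export
burst_power <- function(rec, events, band = c(8, 30)) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!nrow(events)) {
    events$normalised_power_uv2 <- numeric(0)
    return(events)
  }
  dur_total <- recording_duration(rec)
  if (any(events$onset_s < 0 | events$offset_s > dur_total + 1e-9))
    stop("event outside recording bounds")
  bp <- bandpass_recording(rec, band[1L], band[2L])
  fs <- rec$sampling_rate
  n <- ncol(rec$signal)
  events$normalised_power_uv2 <- vapply(seq_len(nrow(events)), function(k) {
    i <- match(events$channel[k], rec$channel_labels)
    if (is.na(i)) stop("event channel not in recording: ", events$channel[k])
    i0 <- floor(events$onset_s[k] * fs) + 1L
    i1 <- min(n, ceiling(events$offset_s[k] * fs))
    mean(bp$signal[i, i0:i1]^2)
  }, numeric(1L))
  events
}

#' Per-channel burst summary statistics
#'
#' Median burst duration, occurrence rate (events per artifact-free second),
#' and median and mean normalised power per channel. Channels with no events
#' get rate 0 and `NA` medians.
#'
#' @param events data.frame of burst events (with `normalised_power_uv2` if
#'   power summaries are wanted).
#' @param clean_seconds artifact-free recording duration in seconds, either a
#'   scalar or a named vector per channel (see [clean_duration()]).
#' @param channels channels to summarise (default: those present in `events`).
#' @return data.frame with one row per channel: `channel`, `n_bursts`,
#'   `median_duration_s`, `rate_per_s`, `median_power_uv2`, `mean_power_uv2`.
#' @export
summarise_bursts <- function(events, clean_seconds, channels = NULL) {
  if (is.null(channels)) channels <- unique(events$channel)
  if (!length(channels)) stop("no channels to summarise")
  rows <- lapply(channels, function(ch) {
    ev <- events[events$channel == ch, , drop = FALSE]
    cs <- if (length(clean_seconds) > 1L) clean_seconds[[ch]] else clean_seconds
    pw <- if ("normalised_power_uv2" %in% names(ev)) ev$normalised_power_uv2
          else rep(NA_real_, nrow(ev))
    data.frame(channel = ch, n_bursts = nrow(ev),
               median_duration_s = if (nrow(ev)) stats::median(ev$duration_s)
                                   else NA_real_,
               rate_per_s = nrow(ev) / cs,
               median_power_uv2 = if (nrow(ev)) stats::median(pw) else NA_real_,
               mean_power_uv2 = if (nrow(ev)) mean(pw) else NA_real_)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Match detected events against planted ground truth
#'
#' A true burst counts as recalled when some detected event at the same
#' channel overlaps at least `min_overlap` of its duration; a detected event
#' counts as correct when some true burst overlaps at least `min_overlap` of
#' the detection's duration.
#'
#' @param detected data.frame of detected events (`channel`, `onset_s`,
#'   `offset_s`).
#' @param truth data.frame of planted bursts (same columns; artifact rows are
#'   ignored if a `kind` column is present).
#' @param min_overlap overlap fraction required (default 0.5).
#' @return list with `recall`, `precision`, `n_truth`, `n_detected`.
#' @export
match_events <- function(detected, truth, min_overlap = 0.5) {
  if ("kind" %in% names(truth)) truth <- truth[truth$kind == "burst", ]
  ov_frac <- function(ev, others, denom) {
    if (!nrow(others)) return(0)
    ov <- pmin(ev$offset_s, others$offset_s) - pmax(ev$onset_s, others$onset_s)
    max(ov) / denom
  }
  hit_t <- vapply(seq_len(nrow(truth)), function(k) {
    tr <- truth[k, ]
    dd <- detected[detected$channel == tr$channel, , drop = FALSE]
    ov_frac(tr, dd, tr$offset_s - tr$onset_s) >= min_overlap
  }, logical(1L))
  hit_d <- vapply(seq_len(nrow(detected)), function(k) {
    de <- detected[k, ]
    tt <- truth[truth$channel == de$channel, , drop = FALSE]
    ov_frac(de, tt, de$offset_s - de$onset_s) >= min_overlap
  }, logical(1L))
  list(recall = if (nrow(truth)) mean(hit_t) else NA_real_,
       precision = if (nrow(detected)) mean(hit_d) else NA_real_,
       n_truth = nrow(truth), n_detected = nrow(detected))
}
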
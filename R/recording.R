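#' EEG recording container
#'
#' Bundles a multichannel EEG signal with its channel labels, sampling rate and
#' a per-sample artifact mask. The mask marks samples excluded from analysis;
#' the signal itself is never modified by masking, so hour-scale timestamps
#' (needed for sleep-cycle periodicity) remain valid.
#'
#' @param signal numeric matrix, channels x samples, in microvolts.
#' @param channel_labels character vector of 10/20-system names, one per row.
#' @param sampling_rate sampling rate in Hz.
#' @param artifact_mask logical vector, one element per sample column;
#'   `TRUE` = excluded. Defaults to all-`FALSE`.
#' @param start_time offset of the first sample in seconds (default 0).
#'
#' @return An object of class `eeg_recording`: a list with fields `signal`,
#'   `channel_labels`, `sampling_rate`, `artifact_mask`, `start_time`.
#' @export
eeg_recording <- function(signal, channel_labels, sampling_rate,
                          artifact_mask = NULL, start_time = 0) {
  signal <- as.matrix(signal)
  if (length(channel_labels) != nrow(signal))
    stop("need one channel label per signal row")
  if (anyDuplicated(channel_labels))
    stop("duplicate channel labels")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number")
  if (is.null(artifact_mask)) artifact_mask <- rep(FALSE, ncol(signal))
  if (length(artifact_mask) != ncol(signal))
    stop("artifact_mask must have one element per sample")
  rownames(signal) <- channel_labels
  structure(
    list(signal = signal,
         channel_labels = as.character(channel_labels),
         sampling_rate = sampling_rate,
         artifact_mask = as.logical(artifact_mask),
         start_time = start_time),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  n <- ncol(x$signal)
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s, %.1f s clean)\n",
              nrow(x$signal), n, x$sampling_rate,
              n / x$sampling_rate, clean_duration(x)))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Total recording duration in seconds
#' @param rec an `eeg_recording`.
#' @return duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$signal) / rec$sampling_rate

#' Artifact-free duration in seconds
#'
#' @param rec an `eeg_recording`.
#' @return unmasked samples divided by the sampling rate.
#' @export
clean_duration <- function(rec) sum(!rec$artifact_mask) / rec$sampling_rate

#' Seconds currently masked as artifact
#' @param rec an `eeg_recording`.
#' @return masked samples divided by the sampling rate.
#' @export
masked_seconds <- function(rec) sum(rec$artifact_mask) / rec$sampling_rate

#' Mask high-amplitude artifact sections
#'
#' Marks as artifact every sample at which any channel exceeds
#' `amplitude_threshold` in absolute value, expanding each exceedance by `pad`
#' seconds on both sides. This automates the clinical criterion used for
#' neonatal EEG review, where artifact sections are typically defined as
#' exceeding 500 microvolts. Samples are masked, never removed, so the time
#' axis is preserved for periodicity analysis.
#'
#' Masking is idempotent (re-applying the same threshold changes nothing) and
#' monotone (lowering the threshold can only grow the masked set).
#'
#' @param rec an `eeg_recording`.
#' @param amplitude_threshold threshold in microvolts (default 500).
#' @param pad seconds added on each side of every exceedance (default 0.5).
#' @return The recording with an updated `artifact_mask`; the total masked
#'   duration is available via [masked_seconds()].
#' @export
mask_artifacts <- function(rec, amplitude_threshold = 500, pad = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (amplitude_threshold <= 0) stop("amplitude_threshold must be > 0")
  if (pad < 0) stop("pad must be >= 0")
  exceed <- matrixStats_any_abs(rec$signal, amplitude_threshold)
  if (any(exceed)) {
    pad_n <- round(pad * rec$sampling_rate)
    if (pad_n > 0) {
      idx <- which(exceed)
      lo <- pmax(1L, idx - pad_n)
      hi <- pmin(length(exceed), idx + pad_n)
      # expand runs without an O(n * pad) loop
      delta <- integer(length(exceed) + 1L)
      delta[lo] <- delta[lo] + 1L
      delta[hi + 1L] <- delta[hi + 1L] - 1L
      exceed <- cumsum(delta[seq_along(exceed)]) > 0L
    }
    rec$artifact_mask <- rec$artifact_mask | exceed
  }
  rec
}

# TRUE for sample columns where any channel exceeds thr in absolute value
matrixStats_any_abs <- function(m, thr) {
  if (nrow(m) == 1L) abs(m[1L, ]) > thr
  else colSums(abs(m) > thr) > 0L
}

#' Convert a logical mask to an interval table
#'
#' @param mask logical vector (TRUE = masked).
#' @param sampling_rate Hz.
#' @return data.frame with columns `onset_s`, `offset_s`, one row per maximal
#'   masked run (offset exclusive).
#' @export
mask_intervals <- function(mask, sampling_rate) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(onset_s = (starts[keep] - 1L) / sampling_rate,
             offset_s = ends[keep] / sampling_rate)
}
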
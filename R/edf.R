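#' Write an EEG recording to European Data Format (EDF)
#'
#' Minimal EDF writer: one data record per second, 16-bit samples, physical
#' units microvolts. Each channel is scaled to its own symmetric physical
#' range, so quantisation error is at most `max(abs(x))/32767` per channel.
#' Recordings are truncated to a whole number of seconds (with a warning) as
#' EDF records here are fixed at 1 s.
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  ns <- nrow(rec$signal)
  n_rec <- floor(ncol(rec$signal) / fs)
  if (n_rec < 1L) stop("recording shorter than one 1-s EDF record")
  n_keep <- n_rec * fs
  if (n_keep < ncol(rec$signal))
    warning(sprintf("truncating %d trailing samples to whole EDF records",
                    ncol(rec$signal) - n_keep))
  x <- rec$signal[, seq_len(n_keep), drop = FALSE]

  pad <- function(s, w) formatC(substr(s, 1L, w), width = -w)
  con <- file(path, "wb")
  on.exit(close(con))

  writeChar(pad("0", 8L), con, eos = NULL)
  writeChar(pad("X X X X", 80L), con, eos = NULL)            # patient id
  writeChar(pad("Startdate X X X X", 80L), con, eos = NULL)  # recording id
  writeChar(pad("01.01.00", 8L), con, eos = NULL)
  writeChar(pad("00.00.00", 8L), con, eos = NULL)
  writeChar(pad(as.character(256L * (ns + 1L)), 8L), con, eos = NULL)
  writeChar(pad("", 44L), con, eos = NULL)
  writeChar(pad(as.character(n_rec), 8L), con, eos = NULL)
  writeChar(pad("1", 8L), con, eos = NULL)
  writeChar(pad(as.character(ns), 4L), con, eos = NULL)

  pmax_ch <- pmax(apply(abs(x), 1L, max), 1)
  pmax_ch <- signif(pmax_ch * 1.0001, 6L)
  wr_each <- function(vals, w) for (v in vals) writeChar(pad(v, w), con, eos = NULL)
  wr_each(rec$channel_labels, 16L)
  wr_each(rep("AgAgCl electrode", ns), 80L)
  wr_each(rep("uV", ns), 8L)
  wr_each(formatC(-pmax_ch, format = "g", digits = 6L), 8L)
  wr_each(formatC(pmax_ch, format = "g", digits = 6L), 8L)
  wr_each(rep("-32768", ns), 8L)
  wr_each(rep("32767", ns), 8L)
  wr_each(rep("", ns), 80L)
  wr_each(rep(as.character(fs), ns), 8L)
  wr_each(rep("", ns), 32L)

  # digital conversion per channel, then interleave by record
  dig <- round((x + pmax_ch) / (2 * pmax_ch) * 65535 - 32768)
  dig <- pmin(pmax(dig, -32768), 32767)
  storage.mode(dig) <- "integer"
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con,
             size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into an EEG recording
#'
#' Parses the fixed-layout EDF header, reads all data records and rescales to
#' physical units (expected microvolts). All channels must share one sampling
#' rate.
#'
#' @param path EDF file path.
#' @param drop_channels optional character vector of channel labels to remove
#'   (e.g. a channel deleted for poor recording quality). Unknown labels are an
#'   error.
#' @return An [eeg_recording()] with an all-`FALSE` artifact mask.
#' @export
read_recording <- function(path, drop_channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8L)                      # version
  rd(80L); rd(80L); rd(8L); rd(8L)
  rd(8L)                      # header bytes
  rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  if (is.na(n_rec) || is.na(ns) || ns < 1L) stop("not a valid EDF header")

  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1L))
  labels <- rdv(16L)
  rdv(80L)                    # transducer
  rdv(8L)                     # physical dimension
  pmin_ch <- as.numeric(rdv(8L))
  pmax_ch <- as.numeric(rdv(8L))
  dmin <- as.numeric(rdv(8L))
  dmax <- as.numeric(rdv(8L))
  rdv(80L)                    # prefilter
  spr <- as.integer(rdv(8L))  # samples per record
  rdv(32L)

  if (length(unique(spr)) != 1L || rec_dur <= 0)
    stop("mixed sampling rates are not supported")
  fs <- spr[1L] / rec_dur
  n_samp <- n_rec * spr[1L]
  sig <- matrix(0, nrow = ns, ncol = n_samp)
  scale <- (pmax_ch - pmin_ch) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = ns * spr[1L], size = 2L,
                     signed = TRUE, endian = "little")
    cols <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    sig[, cols] <- t(matrix(block, nrow = spr[1L])) * scale +
      (pmin_ch - dmin * scale)
  }
  rec <- eeg_recording(sig, labels, fs)
  if (!is.null(drop_channels)) {
    unknown <- setdiff(drop_channels, rec$channel_labels)
    if (length(unknown))
      stop("unknown channel label(s): ", paste(unknown, collapse = ", "))
    keep <- !(rec$channel_labels %in% drop_channels)
    rec <- eeg_recording(rec$signal[keep, , drop = FALSE],
                         rec$channel_labels[keep], fs,
                         rec$artifact_mask, rec$start_time)
  }
  rec
}

#' Write an event table to a delimited file
#'
#' Tab-separated plain-text output for burst, artifact or ground-truth event
#' tables (columns as produced by [detect_bursts()] or the simulator).
#'
#' @param events data.frame of events.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an event table written by [write_event_table()]
#' @param path file path.
#' @return data.frame.
#' @export
read_event_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
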
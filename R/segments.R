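#' Quality classes
#'
#' `quality_levels()` returns the three target classes ordered from worst
#' to best; `quality_labels()` additionally contains `"MED_MUSC"`, the
#' muscular refinement of `"MED_Q"`.
#'
#' @return Character vector of class names.
#' @export
quality_levels <- function() c("LOW_Q", "MED_Q", "HIGH_Q")

#' @rdname quality_levels
#' @export
quality_labels <- function() c("LOW_Q", "MED_Q", "MED_MUSC", "HIGH_Q")

# collapse the 4-level labelling to the 3 classifier classes
collapse_labels <- function(labels) {
  labels[labels == "MED_MUSC"] <- "MED_Q"
  labels
}

#' Construct a one-second EEG segment
#'
#' A segment is the atomic unit of the pipeline: exactly one second of
#' single-channel EEG, i.e. `sampling_rate` finite samples in microvolts.
#'
#' @param samples Numeric vector of amplitudes in microvolts; its length
#'   must equal `sampling_rate`.
#' @param sampling_rate Sampling rate in Hz (positive integer).
#' @param origin_index Ordinal position of the segment in its source
#'   recording (0-based).
#' @param channel_name Text label of the source channel.
#' @return An object of class `eeg_segment`.
#' @export
eeg_segment <- function(samples, sampling_rate, origin_index = 0L,
                        channel_name = "EEG") {
  sampling_rate <- as.integer(sampling_rate)
  if (is.na(sampling_rate) || sampling_rate <= 0L)
    stop("'sampling_rate' must be a positive integer (Hz)")
  samples <- as.numeric(samples)
  if (length(samples) != sampling_rate)
    stop("a segment must hold exactly one second of data: expected ",
         sampling_rate, " samples, got ", length(samples))
  if (!all(is.finite(samples)))
    stop("segment samples must be finite (no NA/NaN/Inf)")
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         origin_index = as.integer(origin_index),
         channel_name = as.character(channel_name)),
    class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %s #%d: %d samples @ %d Hz, RMS %.2f uV\n",
              x$channel_name, x$origin_index, length(x$samples),
              x$sampling_rate, sqrt(mean(x$samples^2))))
  invisible(x)
}

#' Cut a recording into one-second non-overlapping segments
#'
#' The recording is partitioned into consecutive windows of exactly
#' `sampling_rate` samples; a trailing remainder shorter than one second
#' is discarded.
#'
#' @param recording Numeric vector, single-channel EEG in microvolts.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_name Channel label stored in each segment.
#' @return List of [eeg_segment()] objects with consecutive
#'   `origin_index` starting at 0.
#' @export
segment_recording <- function(recording, sampling_rate,
                              channel_name = "EEG") {
  sampling_rate <- as.integer(sampling_rate)
  recording <- as.numeric(recording)
  if (!all(is.finite(recording)))
    stop("recording contains non-finite samples")
  if (length(recording) < sampling_rate)
    stop("recording too short: need at least one second (",
         sampling_rate, " samples), got ", length(recording))
  n_seg <- length(recording) %/% sampling_rate
  lapply(seq_len(n_seg) - 1L, function(i) {
    eeg_segment(recording[(i * sampling_rate + 1L):((i + 1L) * sampling_rate)],
                sampling_rate, origin_index = i, channel_name = channel_name)
  })
}

#' Canonical EEG frequency bands
#'
#' Delta, theta, alpha, beta and gamma band edges. The gamma upper edge is
#' capped at 0.99 times the Nyquist frequency when the sampling rate is too
#' low to carry it (at 250 Hz the printed 28--110 Hz band is kept as is).
#'
#' @param sampling_rate Sampling rate in Hz.
#' @return Data frame with columns `name`, `f_lo`, `f_hi` (Hz).
#' @export
eeg_bands <- function(sampling_rate = 250) {
  nyq <- sampling_rate / 2
  b <- data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    f_lo = c(0.5, 4, 8, 13, 28),
    f_hi = c(4, 8, 13, 28, 110),
    stringsAsFactors = FALSE)
  b$f_hi <- pmin(b$f_hi, 0.99 * nyq)
  b[b$f_lo < nyq & b$f_lo < b$f_hi, , drop = FALSE]
}
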
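# IIR designs are cached; designing Butterworth/biquad coefficients is
# cheap but happens once per (type, rate, edge) combination.
get_filter <- function(key, design) {
  if (!is.null(.filter_cache[[key]])) return(.filter_cache[[key]])
  f <- design()
  .filter_cache[[key]] <- f
  f
}

# zero-phase filtering with odd-reflection padding at both ends, so the
# filter transient settles outside the segment (1-s segments are short
# relative to a high-Q notch impulse response)
filtfilt_padded <- function(b, a, x) {
  n <- length(x)
  p <- min(n - 1L, 250L)
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- signal::filtfilt(b, a, xp)
  y[(p + 1):(p + n)]
}

# RBJ-style biquad notch at f0 with quality factor Q
design_notch <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Remove DC offset and mains interference from a segment
#'
#' Subtracts the segment mean and applies a biquad notch (quality factor
#' 30) centred at `notch_freq` — the standard first step for wearable EEG,
#' where power-line pickup at 50 Hz (60 Hz in other mains regions) is
#' ubiquitous. The notch gain is applied in the frequency domain (the
#' squared magnitude of the biquad on the DFT grid), which is exactly
#' zero-phase and free of the settling transient a high-Q IIR exhibits on
#' a one-second segment.
#'
#' @param seg An [eeg_segment()].
#' @param notch_freq Notch centre frequency in Hz; must be below Nyquist.
#' @param Q Notch quality factor (centre frequency / -3 dB bandwidth).
#' @return The filtered [eeg_segment()], with zero mean.
#' @export
remove_dc_and_notch <- function(seg, notch_freq = 50, Q = 30) {
  fs <- seg$sampling_rate
  if (notch_freq >= fs / 2)
    stop("notch frequency (", notch_freq, " Hz) must be below Nyquist (",
         fs / 2, " Hz)")
  x <- seg$samples - mean(seg$samples)
  key <- sprintf("notchg_%g_%d_%g_%d", notch_freq, fs, Q, length(x))
  gain <- get_filter(key, function() {
    # squared magnitude of the biquad on the DFT grid: applying the
    # notch in the frequency domain is exactly zero-phase and avoids the
    # settling transient a high-Q IIR exhibits on a one-second segment
    flt <- design_notch(notch_freq, fs, Q)
    z <- exp(-2i * pi * (seq_along(x) - 1) / length(x))
    h <- (flt$b[1] + flt$b[2] * z + flt$b[3] * z^2) /
      (flt$a[1] + flt$a[2] * z + flt$a[3] * z^2)
    Mod(h)^2
  })
  y <- Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / length(x)
  y <- y - mean(y)
  out <- seg
  out$samples <- y
  out
}

#' Band-pass filter a segment
#'
#' Zero-phase 4th-order Butterworth band-pass (applied forward and
#' backward, so no group delay). Band edges above Nyquist are capped at
#' 0.99 x Nyquist.
#'
#' @param seg An [eeg_segment()].
#' @param band One row of [eeg_bands()] (or any list with `f_lo`, `f_hi`
#'   in Hz).
#' @param order Butterworth order (default 4).
#' @return The band-filtered [eeg_segment()].
#' @export
bandpass_segment <- function(seg, band, order = 4) {
  fs <- seg$sampling_rate
  nyq <- fs / 2
  f_lo <- as.numeric(band$f_lo)
  f_hi <- min(as.numeric(band$f_hi), 0.99 * nyq)
  if (f_lo >= nyq)
    stop("band lower edge (", f_lo, " Hz) is at or above Nyquist (",
         nyq, " Hz)")
  if (f_lo >= f_hi) stop("invalid band: f_lo >= f_hi after Nyquist capping")
  key <- sprintf("bp_%g_%g_%d_%d", f_lo, f_hi, fs, order)
  flt <- get_filter(key, function()
    signal::butter(order, c(f_lo, f_hi) / nyq, type = "pass"))
  out <- seg
  out$samples <- filtfilt_padded(flt$b, flt$a, seg$samples)
  out
}

#' Rule-based low-quality prescreen
#'
#' Deterministic rules that route unambiguously bad segments around the
#' classifier: a segment is low quality when more than
#' `constant_fraction` of its samples share one exact value (saturation,
#' flat lines) or when any sample magnitude exceeds `amplitude_limit`.
#' The constant-value rule is evaluated on the raw samples (filtering
#' would break exact equality of a clipped plateau); the amplitude rule is
#' evaluated after DC removal by default.
#'
#' @param seg An [eeg_segment()].
#' @param constant_fraction Fraction of identical samples above which the
#'   segment is declared low quality (strict inequality; default 0.70).
#' @param amplitude_limit Amplitude bound in microvolts (strict
#'   inequality; default 300).
#' @param amplitude_after_dc Logical; evaluate the amplitude rule on the
#'   demeaned samples (default `TRUE`).
#' @return `"LOW_Q"` when a rule fires, otherwise `NA_character_`
#'   ("no override").
#' @export
prescreen_segment <- function(seg, constant_fraction = 0.70,
                              amplitude_limit = 300,
                              amplitude_after_dc = TRUE) {
  stopifnot(constant_fraction > 0, amplitude_limit > 0)
  x <- seg$samples
  modal <- max(tabulate(match(x, unique(x))))
  if (modal / length(x) > constant_fraction) return("LOW_Q")
  amp <- if (amplitude_after_dc) x - mean(x) else x
  if (any(abs(amp) > amplitude_limit)) return("LOW_Q")
  NA_character_
}
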
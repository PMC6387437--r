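#' Welch power spectral density of a segment
#'
#' Averaged modified periodogram with 0.5-s Hann windows and 50% overlap
#' (two to three averages on a one-second segment), zero-padded so the
#' frequency grid spacing is at most 1 Hz. The one-sided density is scaled
#' so that `sum(psd) * df` equals the mean power of the (zero-mean) input.
#'
#' @param x An [eeg_segment()] or a numeric vector.
#' @param sampling_rate Sampling rate in Hz (ignored when `x` is a
#'   segment).
#' @param window_sec Window length in seconds (default 0.5).
#' @param overlap Fractional window overlap (default 0.5).
#' @return An object of class `eeg_psd`: list with `freq` (Hz), `psd`
#'   (uV^2/Hz) and `df` (grid spacing, Hz).
#' @export
welch_psd <- function(x, sampling_rate = NULL, window_sec = 0.5,
                      overlap = 0.5) {
  if (inherits(x, "eeg_segment")) {
    sampling_rate <- x$sampling_rate
    x <- x$samples
  }
  if (is.null(sampling_rate)) stop("'sampling_rate' is required")
  fs <- sampling_rate
  n <- length(x)
  L <- min(n, max(8L, round(window_sec * fs)))
  step <- max(1L, floor(L * (1 - overlap)))
  starts <- seq.int(1L, n - L + 1L, by = step)
  nfft <- max(L, as.integer(fs))        # grid spacing fs/nfft <= 1 Hz
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))  # Hann
  U <- sum(w^2)
  n_keep <- nfft %/% 2L + 1L
  acc <- numeric(n_keep)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)] * w
    X <- stats::fft(c(seg, numeric(nfft - L)))
    P <- (Mod(X)^2 / (fs * U))[seq_len(n_keep)]
    # fold the two-sided density into one-sided
    if (nfft %% 2L == 0L) P[2:(n_keep - 1L)] <- 2 * P[2:(n_keep - 1L)]
    else P[2:n_keep] <- 2 * P[2:n_keep]
    acc <- acc + P
  }
  structure(list(freq = (seq_len(n_keep) - 1) * fs / nfft,
                 psd = acc / length(starts),
                 df = fs / nfft),
            class = "eeg_psd")
}

#' @export
print.eeg_psd <- function(x, ...) {
  cat(sprintf("<eeg_psd> %d bins, 0-%.1f Hz (df = %.3g Hz), total power %.3g uV^2\n",
              length(x$freq), max(x$freq), x$df, sum(x$psd) * x$df))
  invisible(x)
}
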
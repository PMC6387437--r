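rms <- function(x) sqrt(mean(x^2))

# coloured noise with one-sided amplitude shaping |X(f)| ~ shape(f)
shaped_noise <- function(n, fs, shape) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                 # mirror for the negative frequencies
  g <- shape(f)
  g[1] <- 0                            # no DC
  y <- Re(stats::fft(X * g, inverse = TRUE)) / n
  y / max(rms(y), 1e-12)
}

#' Generate a clean surrogate resting-EEG segment
#'
#' One second of 1/f-type background (power exponent 1) plus a
#' narrow-band alpha oscillation (centre 10 Hz, bandwidth about 2 Hz)
#' contributing a relative power drawn uniformly in 0.2--0.4. The segment
#' RMS is drawn uniformly in 10--30 microvolts; amplitudes are kept below
#' 100 microvolts (segments whose crest would exceed 95 are rescaled).
#' Deterministic under `seed`.
#'
#' @param seed Integer random seed for this segment.
#' @param sampling_rate Sampling rate in Hz (>= 128).
#' @param origin_index Stored segment index.
#' @return An [eeg_segment()].
#' @export
generate_clean_segment <- function(seed, sampling_rate = 250,
                                   origin_index = 0L) {
  if (sampling_rate < 128) stop("'sampling_rate' must be at least 128 Hz")
  fs <- sampling_rate
  with_local_seed(seed, {
    pink <- shaped_noise(fs, fs, function(f) 1 / sqrt(pmax(f, 1)))
    alpha <- shaped_noise(fs, fs, function(f) exp(-(f - 10)^2 / (2 * 1^2)))
    a <- stats::runif(1, 0.2, 0.4)
    x <- sqrt(1 - a) * pink + sqrt(a) * alpha
    x <- x * stats::runif(1, 10, 30) / rms(x)
    if (max(abs(x)) > 95) x <- x * 95 / max(abs(x))
    eeg_segment(x, fs, origin_index = origin_index, channel_name = "SIM")
  })
}

#' Generate a muscular (EMG) artefact waveform
#'
#' Band-limited 20--45 Hz noise burst of uniform random duration
#' 0.3--0.7 s with a Hann envelope, random onset so the burst fits inside
#' the one-second window, zero elsewhere.
#'
#' @param seed Integer random seed.
#' @param sampling_rate Sampling rate in Hz (>= 128).
#' @return Numeric artefact waveform of length `sampling_rate` with
#'   attributes `duration` and `onset` (seconds).
#' @export
generate_muscular_artefact <- function(seed, sampling_rate = 250) {
  if (sampling_rate < 128) stop("'sampling_rate' must be at least 128 Hz")
  fs <- sampling_rate
  with_local_seed(seed, {
    dur <- stats::runif(1, 0.3, 0.7)
    n_burst <- round(dur * fs)
    onset <- sample.int(fs - n_burst + 1L, 1) - 1L
    # band-limited noise by spectral shaping with raised-cosine edges
    # (3 Hz transition inside 20-45): the Hann burst envelope then keeps
    # nearly all power inside the nominal 20-45 Hz band
    band <- shaped_noise(fs, fs, function(f) {
      g <- numeric(length(f))
      g[f >= 23 & f <= 42] <- 1
      lo <- f >= 20 & f < 23
      g[lo] <- 0.5 - 0.5 * cos(pi * (f[lo] - 20) / 3)
      hi <- f > 42 & f <= 45
      g[hi] <- 0.5 + 0.5 * cos(pi * (f[hi] - 42) / 3)
      g
    })
    env <- numeric(fs)
    env[(onset + 1L):(onset + n_burst)] <-
      0.5 - 0.5 * cos(2 * pi * (0:(n_burst - 1)) / (n_burst - 1))
    v <- band * env
    structure(v, duration = n_burst / fs, onset = onset / fs)
  })
}

#' Generate an ocular (EOG) artefact waveform
#'
#' Parametric templates of eye activity: `"blink"` is a smooth biphasic
#' pulse (positive lobe with a shallower negative rebound) of total width
#' 200--400 ms, zero outside the event, with spectral content below
#' 5 Hz; `"slow"` emulates a slow vertical/horizontal eye movement — a
#' sustained electro-oculographic level shift: a smooth monotone
#' half-period transition between two plateaus, lasting 0.5--1 s
#' (content below 2 Hz, at most two zero crossings). Random polarity and
#' onset.
#'
#' @param seed Integer random seed.
#' @param kind `"blink"` or `"slow"`.
#' @param sampling_rate Sampling rate in Hz (>= 128).
#' @return Numeric artefact waveform of length `sampling_rate`.
#' @export
generate_eog_artefact <- function(seed, kind = c("blink", "slow"),
                                  sampling_rate = 250) {
  kind <- match.arg(kind)
  if (sampling_rate < 128) stop("'sampling_rate' must be at least 128 Hz")
  fs <- sampling_rate
  with_local_seed(seed, {
    v <- numeric(fs)
    if (kind == "blink") {
      width <- stats::runif(1, 0.2, 0.4)
      n_ev <- round(width * fs)
      n_main <- round(0.65 * n_ev)
      n_reb <- n_ev - n_main
      shape <- c(sin(pi * seq_len(n_main) / (n_main + 1))^2,
                 -0.35 * sin(pi * seq_len(n_reb) / (n_reb + 1))^2)
      onset <- sample.int(fs - n_ev + 1L, 1) - 1L
      pol <- sample(c(-1, 1), 1)
      v[(onset + 1L):(onset + n_ev)] <- pol * shape
    } else {
      # gaze shift: potential moves from one level to another and holds
      dur <- stats::runif(1, 0.5, 1)
      n_ev <- min(fs, round(dur * fs))
      onset <- sample.int(fs - n_ev + 1L, 1) - 1L
      pol <- sample(c(-1, 1), 1)
      if (onset > 0) v[1:onset] <- -1
      v[(onset + 1L):(onset + n_ev)] <-
        sin(pi * seq_len(n_ev) / (n_ev + 1) - pi / 2)
      if (onset + n_ev < fs) v[(onset + n_ev + 1L):fs] <- 1
      v <- pol * v
    }
    v
  })
}

#' Generate an extreme-value artefact waveform
#'
#' Simulates large movements and electrode clipping: 3 to 5 extreme
#' points with magnitudes uniform in 100--400 microvolts (random signs),
#' consecutive spacings uniform in 10--100 ms, joined by monotone cubic
#' interpolation (no overshoot beyond the extreme values) and zero
#' elsewhere.
#'
#' @param seed Integer random seed.
#' @param sampling_rate Sampling rate in Hz (>= 128).
#' @return Numeric artefact waveform of length `sampling_rate` with
#'   attributes `n_points`, `amplitudes` and `spacings_ms`.
#' @export
generate_extreme_values <- function(seed, sampling_rate = 250) {
  if (sampling_rate < 128) stop("'sampling_rate' must be at least 128 Hz")
  fs <- sampling_rate
  with_local_seed(seed, {
    n_pts <- sample(3:5, 1)
    amps <- stats::runif(n_pts, 100, 400) * sample(c(-1, 1), n_pts, TRUE)
    # spacings snapped to the sample grid, staying inside 10-100 ms
    lo <- ceiling(0.010 * fs); hi <- floor(0.100 * fs)
    gaps <- round(stats::runif(n_pts - 1, 0.010, 0.100) * fs)
    gaps <- pmin(pmax(gaps, lo), hi)
    margin <- max(2L, round(0.02 * fs))
    span <- sum(gaps)
    onset <- sample.int(fs - span - 2L * margin - 1L, 1) + margin
    idx <- onset + c(0L, cumsum(gaps))
    knots_t <- c(onset - margin, idx, idx[n_pts] + margin)
    knots_v <- c(0, amps, 0)
    # piecewise cubic Hermite with zero slope at every knot (smoothstep):
    # C1, monotone between knots, never overshoots the extreme values
    v <- numeric(fs)
    for (j in seq_len(length(knots_t) - 1)) {
      tt <- knots_t[j]:knots_t[j + 1]
      u <- (tt - knots_t[j]) / (knots_t[j + 1] - knots_t[j])
      v[tt + 1L] <- knots_v[j] +
        (knots_v[j + 1] - knots_v[j]) * (3 * u^2 - 2 * u^3)
    }
    structure(v, n_points = n_pts, amplitudes = amps,
              spacings_ms = gaps / fs * 1000)
  })
}

#' Superimpose an artefact on a clean segment at a target SNR
#'
#' Returns `b + lambda * v` with
#' `lambda = RMS(b) / (RMS(v) * 10^(snr_db / 20))`, so the achieved
#' `20 log10(RMS(b) / RMS(lambda v))` equals `snr_db` exactly (0 dB means
#' equal RMS). RMS of the artefact is taken over the full one-second
#' window.
#'
#' @param b Clean [eeg_segment()].
#' @param v Artefact waveform (numeric, same length).
#' @param snr_db Target signal-to-noise ratio in dB.
#' @return The contaminated [eeg_segment()] with attributes `snr_db` and
#'   `lambda`.
#' @export
mix_at_snr <- function(b, v, snr_db) {
  x <- b$samples
  v <- as.numeric(v)
  if (length(v) != length(x)) stop("artefact and segment lengths differ")
  rv <- rms(v)
  if (rv == 0) stop("artefact waveform has zero RMS")
  lambda <- rms(x) / (rv * 10^(snr_db / 20))
  out <- b
  out$samples <- x + lambda * v
  attr(out, "snr_db") <- snr_db
  attr(out, "lambda") <- lambda
  out
}

#' Dataset generation recipe
#'
#' Default composition mirrors the validation design: 300 clean
#' (`HIGH_Q`), 100 blink + 100 slow eye movement (`MED_Q`), 100 muscular
#' bursts (`MED_MUSC`) at SNR uniform in 0--15 dB, and 300 extreme-value
#' excerpts (`LOW_Q`) at SNR uniform in -10--0 dB.
#'
#' @param n_clean,n_blink,n_slow,n_muscular,n_extreme Segment counts.
#' @param snr_artefact SNR range (dB) for the ocular and muscular
#'   patterns.
#' @param snr_extreme SNR range (dB) for the extreme-value pattern.
#' @param sampling_rate Sampling rate in Hz.
#' @param seed Master seed; clean carriers and artefact waveforms use
#'   independent derived streams.
#' @return A `dataset_config` list.
#' @export
dataset_config <- function(n_clean = 300, n_blink = 100, n_slow = 100,
                           n_muscular = 100, n_extreme = 300,
                           snr_artefact = c(0, 15), snr_extreme = c(-10, 0),
                           sampling_rate = 250, seed = 1) {
  cfg <- list(n_clean = n_clean, n_blink = n_blink, n_slow = n_slow,
              n_muscular = n_muscular, n_extreme = n_extreme,
              snr_artefact = sort(as.numeric(snr_artefact)),
              snr_extreme = sort(as.numeric(snr_extreme)),
              sampling_rate = as.integer(sampling_rate),
              seed = as.integer(seed))
  counts <- unlist(cfg[1:5])
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all segment counts must be positive integers")
  if (length(cfg$snr_artefact) != 2 || length(cfg$snr_extreme) != 2)
    stop("SNR ranges must have two endpoints")
  structure(cfg, class = "dataset_config")
}

#' Build a labelled synthetic dataset
#'
#' Generates clean surrogate EEG segments and artefact-contaminated
#' segments at controlled SNR according to a [dataset_config()]. Every
#' segment records its generating seeds and SNR in the manifest, and
#' rebuilding from the same configuration reproduces the dataset
#' bit-identically.
#'
#' @param config A [dataset_config()].
#' @return Object of class `labelled_dataset`: list with `segments`,
#'   `labels` (in [quality_labels()]), `snrs` (`NA` for clean segments)
#'   and `manifest` (config plus a per-segment generation table).
#' @export
build_dataset <- function(config = dataset_config()) {
  stopifnot(inherits(config, "dataset_config"))
  fs <- config$sampling_rate
  patterns <- c(rep("clean", config$n_clean),
                rep("eog_blink", config$n_blink),
                rep("eog_slow", config$n_slow),
                rep("muscular", config$n_muscular),
                rep("extreme_values", config$n_extreme))
  label_of <- c(clean = "HIGH_Q", eog_blink = "MED_Q", eog_slow = "MED_Q",
                muscular = "MED_MUSC", extreme_values = "LOW_Q")
  n <- length(patterns)
  carrier_seed <- vapply(seq_len(n), function(i) derive_seed(config$seed, i), 0L)
  artefact_seed <- vapply(seq_len(n), function(i)
    derive_seed(config$seed + 1e6, i), 0L)
  snr <- rep(NA_real_, n)
  art_idx <- patterns %in% c("eog_blink", "eog_slow", "muscular")
  ext_idx <- patterns == "extreme_values"
  snr[art_idx] <- with_local_seed(derive_seed(config$seed, 0), stats::runif(
    sum(art_idx), config$snr_artefact[1], config$snr_artefact[2]))
  snr[ext_idx] <- with_local_seed(derive_seed(config$seed + 2e6, 0),
    stats::runif(sum(ext_idx), config$snr_extreme[1], config$snr_extreme[2]))
  segments <- vector("list", n)
  for (i in seq_len(n)) {
    b <- generate_clean_segment(carrier_seed[i], fs, origin_index = i - 1L)
    segments[[i]] <- switch(
      patterns[i],
      clean = b,
      eog_blink = mix_at_snr(b, generate_eog_artefact(artefact_seed[i],
                                                      "blink", fs), snr[i]),
      eog_slow = mix_at_snr(b, generate_eog_artefact(artefact_seed[i],
                                                     "slow", fs), snr[i]),
      muscular = mix_at_snr(b, generate_muscular_artefact(artefact_seed[i],
                                                          fs), snr[i]),
      extreme_values = mix_at_snr(b, generate_extreme_values(artefact_seed[i],
                                                             fs), snr[i]))
  }
  structure(
    list(segments = segments,
         labels = unname(label_of[patterns]),
         snrs = snr,
         manifest = list(config = config,
                         table = data.frame(pattern = patterns,
                                            carrier_seed = carrier_seed,
                                            artefact_seed = artefact_seed,
                                            snr_db = snr))),
    class = "labelled_dataset")
}

#' @export
print.labelled_dataset <- function(x, ...) {
  tab <- table(factor(x$labels, levels = quality_labels()))
  cat(sprintf("<labelled_dataset> %d segments @ %d Hz: %s\n",
              length(x$segments), x$segments[[1]]$sampling_rate,
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}
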
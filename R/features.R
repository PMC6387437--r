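# numerical floor for logs and ratios on power values (uV^2)
.pow_eps <- 1e-12

moment_stats <- function(x) {
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v <= 0) return(c(max = max(abs(x - m)), sd = 0, kurtosis = 0, skewness = 0))
  c(max = max(abs(x)),
    sd = stats::sd(x),
    kurtosis = mean((x - m)^4) / v^2,   # Pearson: Gaussian -> 3
    skewness = mean((x - m)^3) / v^1.5)
}

#' Time-domain features of a segment
#'
#' Maximum absolute amplitude, standard deviation, kurtosis (Pearson
#' convention, Gaussian = 3) and skewness, computed on the raw segment and
#' on each band-filtered version (delta, theta, alpha, beta, gamma):
#' 24 values. Zero-variance inputs yield 0 for kurtosis and skewness.
#'
#' @param seg An [eeg_segment()] (DC-removed).
#' @param bands Band table from [eeg_bands()].
#' @return Named numeric vector (partial feature vector).
#' @export
time_features <- function(seg, bands = eeg_bands(seg$sampling_rate)) {
  out <- c(time_stats_named(seg$samples, "raw"))
  for (i in seq_len(nrow(bands))) {
    bx <- bandpass_segment(seg, bands[i, ])
    out <- c(out, time_stats_named(bx$samples, bands$name[i]))
  }
  out
}

time_stats_named <- function(x, suffix) {
  s <- moment_stats(x)
  names(s) <- paste0("time_", c("max", "sd", "kurtosis", "skewness"), "_", suffix)
  s
}

band_power <- function(p, lo, hi) {
  sel <- p$freq >= lo & p$freq < hi
  sum(p$psd[sel]) * p$df
}

#' Frequency-domain features from a power spectral density
#'
#' Per band: absolute, log (natural log of power + 1e-12) and relative
#' power (band power over the total in 0.5 Hz to min(110, Nyquist)).
#' Global descriptors: total power, peak frequency, spectral centroid,
#' 95% spectral edge frequency, spectral flatness (geometric over
#' arithmetic mean), the gamma over (delta+theta+alpha+beta) power ratio,
#' and the first four cepstral-style coefficients (inverse DFT of the log
#' PSD). An all-zero PSD yields zero relative powers and descriptors.
#'
#' @param psd An `eeg_psd` from [welch_psd()].
#' @param bands Band table from [eeg_bands()].
#' @return Named numeric vector (partial feature vector).
#' @export
frequency_features <- function(psd, bands) {
  if (any(psd$psd < 0)) stop("PSD must be non-negative")
  # half-open bands [lo, hi) partition [0.5, gamma hi]; the last band is
  # closed at the top so total power is the exact sum of band powers
  bp <- vapply(seq_len(nrow(bands)), function(i) {
    hi <- bands$f_hi[i]
    if (i == nrow(bands)) hi <- hi + psd$df
    band_power(psd, bands$f_lo[i], hi)
  }, 0)
  total <- sum(bp)
  names(bp) <- bands$name
  rel <- if (total > 0) bp / total else rep(0, length(bp))
  pos <- psd$freq > 0
  pw <- psd$psd[pos]
  fq <- psd$freq[pos]
  if (total > 0 && sum(pw) > 0) {
    peak <- fq[which.max(pw)]
    centroid <- sum(fq * pw) / sum(pw)
    cum <- cumsum(pw) / sum(pw)
    edge95 <- fq[which(cum >= 0.95)[1]]
    flat <- exp(mean(log(pw + .pow_eps))) / mean(pw + .pow_eps)
  } else {
    peak <- centroid <- edge95 <- flat <- 0
  }
  low <- sum(bp[names(bp) != "gamma"])
  gratio <- if (low > 0) unname(bp["gamma"]) / low else 0
  logp <- log(psd$psd + .pow_eps)
  cep <- Re(stats::fft(logp, inverse = TRUE)) / length(logp)
  out <- c(bp, log(bp + .pow_eps), rel,
           total, peak, centroid, edge95, flat, gratio, cep[2:5])
  names(out) <- c(paste0("pow_", bands$name), paste0("logpow_", bands$name),
                  paste0("relpow_", bands$name),
                  "total_power", "peak_freq", "spec_centroid", "spec_edge95",
                  "spec_flatness", "gamma_ratio",
                  paste0("cepstrum_", 1:4))
  out
}

#' Entropy features of a segment
#'
#' Shannon entropy of the amplitude histogram (64 equal-width bins over
#' the segment range, bits), spectral entropy (Shannon entropy of the PSD
#' normalised to a probability distribution, divided by the log of the
#' number of bins, so in \[0, 1\]) and singular value decomposition
#' entropy of the delay-embedding matrix (dimension 10, delay 1).
#' Zero-variance segments yield 0 for all three.
#'
#' @param seg An [eeg_segment()].
#' @param psd Optional precomputed `eeg_psd` (computed if missing).
#' @param n_bins Histogram bin count (default 64).
#' @param embed_dim,embed_delay Delay-embedding parameters for the SVD
#'   entropy (defaults 10 and 1).
#' @return Named numeric vector with `shannon_entropy`,
#'   `spectral_entropy`, `svd_entropy`.
#' @export
entropy_features <- function(seg, psd = NULL, n_bins = 64,
                             embed_dim = 10, embed_delay = 1) {
  x <- seg$samples
  if (is.null(psd)) psd <- welch_psd(seg)
  if (stats::var(x) <= 0) {
    out <- c(0, 0, 0)
  } else {
    counts <- tabulate(
      pmin(n_bins, 1L + floor((x - min(x)) / (diff(range(x)) / n_bins))),
      nbins = n_bins)
    p <- counts / sum(counts)
    h_amp <- -sum(p[p > 0] * log2(p[p > 0]))
    pw <- psd$psd[psd$freq > 0]
    h_spec <- if (sum(pw) > 0) {
      q <- pw / sum(pw)
      -sum(q[q > 0] * log(q[q > 0])) / log(length(q))
    } else 0
    n_rows <- length(x) - (embed_dim - 1) * embed_delay
    emb <- sapply(seq_len(embed_dim), function(j)
      x[(1 + (j - 1) * embed_delay):((j - 1) * embed_delay + n_rows)])
    s <- svd(emb, nu = 0, nv = 0)$d
    h_svd <- if (sum(s) > 0) {
      q <- s / sum(s)
      -sum(q[q > 0] * log2(q[q > 0]))
    } else 0
    out <- c(h_amp, h_spec, h_svd)
  }
  names(out) <- c("shannon_entropy", "spectral_entropy", "svd_entropy")
  out
}

#' Canonical feature names
#'
#' Ordered names of the full feature vector computed by
#' [segment_features()]. The set is a registry: time-domain statistics per
#' band, spectral descriptors and entropies (52 features by default).
#'
#' @param bands Band table from [eeg_bands()].
#' @return Character vector of feature names.
#' @export
feature_names <- function(bands = eeg_bands()) {
  c(paste0("time_", rep(c("max", "sd", "kurtosis", "skewness"),
                        nrow(bands) + 1),
           "_", rep(c("raw", bands$name), each = 4)),
    paste0("pow_", bands$name), paste0("logpow_", bands$name),
    paste0("relpow_", bands$name),
    "total_power", "peak_freq", "spec_centroid", "spec_edge95",
    "spec_flatness", "gamma_ratio", paste0("cepstrum_", 1:4),
    "shannon_entropy", "spectral_entropy", "svd_entropy")
}

#' Full feature vector of one segment
#'
#' Concatenates [time_features()], [frequency_features()] and
#' [entropy_features()] in the canonical order of [feature_names()].
#' All values are finite for any finite input (degenerate segments map to
#' documented fallbacks).
#'
#' @param seg An [eeg_segment()] (DC-removed).
#' @param bands Band table from [eeg_bands()].
#' @param psd Optional precomputed `eeg_psd`.
#' @return Named numeric vector.
#' @export
segment_features <- function(seg, bands = eeg_bands(seg$sampling_rate),
                             psd = NULL) {
  if (is.null(psd)) psd <- welch_psd(seg)
  out <- c(time_features(seg, bands),
           frequency_features(psd, bands),
           entropy_features(seg, psd))
  out[!is.finite(out)] <- 0
  out
}

#' Feature matrix for a collection of segments
#'
#' @param segments List of [eeg_segment()] objects (DC-removed).
#' @param bands Band table from [eeg_bands()].
#' @return Numeric matrix, one row per segment, columns named by
#'   [feature_names()].
#' @export
feature_matrix <- function(segments, bands = eeg_bands(segments[[1]]$sampling_rate)) {
  t(vapply(segments, segment_features, numeric(length(feature_names(bands))),
           bands = bands))
}

#' Fit training-set standardization parameters
#'
#' Per-feature mean and standard deviation estimated on the training set
#' only; applying them to the training set itself gives per-feature mean 0
#' and standard deviation 1 (zero-variance features map to 0).
#'
#' @param x Numeric feature matrix (rows = training segments).
#' @return An object of class `standardization_params`.
#' @export
fit_standardization <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 training segments to standardize")
  structure(list(mean = colMeans(x),
                 sd = apply(x, 2, stats::sd),
                 names = colnames(x)),
            class = "standardization_params")
}

#' Apply standardization parameters to a feature matrix
#'
#' @param x Numeric feature matrix with the same columns as the training
#'   set the parameters were fitted on.
#' @param params A `standardization_params` object from
#'   [fit_standardization()].
#' @return Standardized matrix; zero-variance features become 0.
#' @export
apply_standardization <- function(x, params) {
  x <- as.matrix(x)
  if (!is.null(colnames(x)) && !identical(colnames(x), params$names)) {
    if (!setequal(colnames(x), params$names))
      stop("feature names do not match the standardization parameters")
    x <- x[, params$names, drop = FALSE]
  }
  s <- params$sd
  z <- sweep(x, 2, params$mean, "-")
  keep <- s > 1e-15
  z[, keep] <- sweep(z[, keep, drop = FALSE], 2, s[keep], "/")
  z[, !keep] <- 0
  z
}
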
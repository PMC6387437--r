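# restrict a PSD grid to the EEG-relevant range 0 < f < 40 Hz
itakura_range <- function(freq, f_max = 40) freq > 0 & freq < f_max

#' Itakura spectral distance
#'
#' Normalised (mean-based) Itakura dissimilarity between two power
#' spectra on a common grid restricted to 0 < f < 40 Hz, the range
#' carrying most EEG information:
#' `d = log(mean(pxx / pyy)) - mean(log(pxx / pyy))`.
#' By Jensen's inequality `d >= 0`, with equality iff the ratio is
#' constant over the grid, so the distance is invariant to a global
#' rescaling of either spectrum. Spectra are floored at `1e-12` before
#' the ratio.
#'
#' @param pxx,pyy Non-negative PSD vectors on the same frequency grid.
#' @param freq Frequency grid in Hz (same length as the spectra).
#' @param f_max Upper edge of the comparison range (default 40 Hz).
#' @return Non-negative scalar.
#' @export
itakura_distance <- function(pxx, pyy, freq, f_max = 40) {
  if (length(pxx) != length(pyy) || length(pxx) != length(freq))
    stop("'pxx', 'pyy' and 'freq' must share one grid")
  sel <- itakura_range(freq, f_max)
  if (!any(sel)) stop("no frequencies in (0, ", f_max, ") Hz on this grid")
  r <- pmax(pxx[sel], .pow_eps) / pmax(pyy[sel], .pow_eps)
  log(mean(r)) - mean(log(r))
}

# all unordered pairwise Itakura distances among the rows of a PSD matrix,
# vectorised: mean_f(p_i/p_j) = (A %*% t(1/A)) / n_f and the log term
# separates into row means of log A
pairwise_itakura <- function(psd_mat, freq, f_max = 40) {
  sel <- itakura_range(freq, f_max)
  a <- pmax(psd_mat[, sel, drop = FALSE], .pow_eps)
  m <- a %*% t(1 / a) / ncol(a)
  lg <- rowMeans(log(a))
  d <- log(m) - outer(lg, lg, "-")
  d[upper.tri(d)]
}

#' Fit a clean-EEG spectral reference
#'
#' Averages the spectra of the high-quality (clean) training segments on
#' the 0--40 Hz grid and summarises the Itakura distances between all
#' unordered pairs of clean segments (their mean and standard deviation
#' later define the muscular detection threshold `T = mean + N * sd`).
#'
#' @param psds List of `eeg_psd` objects, or a numeric matrix with one
#'   PSD per row, from the clean training segments (at least 3).
#' @param freq Frequency grid in Hz (required when `psds` is a matrix).
#' @param f_max Upper edge of the comparison range (default 40 Hz).
#' @return Object of class `spectral_reference` with `freq`,
#'   `mean_clean_psd`, `pairwise_mean`, `pairwise_sd`; the threshold
#'   fields `N` and `T` are unset until [calibrate_reference()].
#' @export
fit_spectral_reference <- function(psds, freq = NULL, f_max = 40) {
  if (is.list(psds) && inherits(psds[[1]], "eeg_psd")) {
    freq <- psds[[1]]$freq
    psds <- t(vapply(psds, function(p) p$psd, numeric(length(freq))))
  }
  psds <- as.matrix(psds)
  if (is.null(freq)) stop("'freq' is required with a PSD matrix")
  if (nrow(psds) < 3)
    stop("need at least 3 clean segments to fit a spectral reference")
  sel <- itakura_range(freq, f_max)
  d <- pairwise_itakura(psds, freq, f_max)
  structure(list(freq = freq[sel],
                 mean_clean_psd = pmax(colMeans(psds[, sel, drop = FALSE]),
                                       .pow_eps),
                 pairwise_mean = mean(d),
                 pairwise_sd = stats::sd(d),
                 n_clean = nrow(psds), f_max = f_max,
                 N = NA_real_, T = NA_real_),
            class = "spectral_reference")
}

#' @export
print.spectral_reference <- function(x, ...) {
  cat(sprintf(paste0("<spectral_reference> %d clean segments, pairwise ",
                     "d_I %.4g +/- %.4g%s\n"),
              x$n_clean, x$pairwise_mean, x$pairwise_sd,
              if (is.finite(x$T)) sprintf(", N = %g, T = %.4g", x$N, x$T)
              else " (uncalibrated)"))
  invisible(x)
}

# Itakura distance of each PSD row to the reference mean clean spectrum
reference_distances <- function(reference, psd_mat, freq) {
  sel <- itakura_range(freq, reference$f_max)
  if (sum(sel) != length(reference$mean_clean_psd) ||
      max(abs(freq[sel] - reference$freq)) > 1e-9)
    stop("PSD frequency grid does not match the spectral reference")
  a <- pmax(psd_mat[, sel, drop = FALSE], .pow_eps)
  r <- sweep(a, 2, reference$mean_clean_psd, "/")
  log(rowMeans(r)) - rowMeans(log(r))
}

#' Calibrate the muscular detection threshold
#'
#' Chooses the multiplier `N` in `T = pairwise_mean + N * pairwise_sd` by
#' scanning a candidate grid and maximising the balanced accuracy of
#' muscular vs non-muscular discrimination among the medium-quality
#' training segments (a segment is called muscular when its Itakura
#' distance to the mean clean spectrum strictly exceeds `T`). Accuracy
#' ties resolve to the smallest `N`.
#'
#' @param reference A `spectral_reference` from [fit_spectral_reference()].
#' @param psds Medium-quality training spectra (list of `eeg_psd` or
#'   matrix of rows).
#' @param is_muscular Logical per spectrum: `TRUE` for muscular
#'   (`MED_MUSC`) training segments; both values must occur.
#' @param freq Frequency grid (required for a matrix).
#' @param n_grid Candidate multipliers (default 0 to 10 by 0.25).
#' @return The `spectral_reference` with `N` and `T` set, plus the
#'   training `balanced_accuracy` reached.
#' @export
calibrate_reference <- function(reference, psds, is_muscular, freq = NULL,
                                n_grid = seq(0, 10, by = 0.25)) {
  if (is.list(psds) && inherits(psds[[1]], "eeg_psd")) {
    freq <- psds[[1]]$freq
    psds <- t(vapply(psds, function(p) p$psd, numeric(length(freq))))
  }
  psds <- as.matrix(psds)
  if (is.null(freq)) stop("'freq' is required with a PSD matrix")
  is_muscular <- as.logical(is_muscular)
  if (!any(is_muscular))
    stop("threshold calibration needs muscular (MED_MUSC) training segments")
  if (all(is_muscular))
    stop("threshold calibration needs non-muscular MED_Q training segments")
  d <- reference_distances(reference, psds, freq)
  best <- -Inf; best_n <- n_grid[1]
  for (N in n_grid) {
    thr <- reference$pairwise_mean + N * reference$pairwise_sd
    pred <- d > thr
    sens <- mean(pred[is_muscular])
    spec <- mean(!pred[!is_muscular])
    bacc <- (sens + spec) / 2
    if (bacc > best + 1e-12) { best <- bacc; best_n <- N }
  }
  reference$N <- best_n
  reference$T <- reference$pairwise_mean + best_n * reference$pairwise_sd
  reference$balanced_accuracy <- best
  reference
}

#' Muscular refinement of a medium-quality segment
#'
#' A segment already classified `MED_Q` is refined to `MED_MUSC` iff the
#' Itakura distance of its spectrum to the mean clean spectrum strictly
#' exceeds the calibrated threshold `T`.
#'
#' @param reference A calibrated `spectral_reference`.
#' @param psd The segment's `eeg_psd` (or a PSD vector with `freq`).
#' @param freq Frequency grid when `psd` is a bare vector.
#' @return `"MED_MUSC"` or `"MED_Q"`.
#' @export
refine_med_q <- function(reference, psd, freq = NULL) {
  if (!is.finite(reference$T))
    stop("spectral reference is not calibrated (run calibrate_reference)")
  if (inherits(psd, "eeg_psd")) { freq <- psd$freq; psd <- psd$psd }
  d <- reference_distances(reference, matrix(psd, nrow = 1), freq)
  if (d > reference$T) "MED_MUSC" else "MED_Q"
}
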
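# Preprocess raw segments once: prescreen on the raw samples, then
# DC/notch removal, feature matrix and Welch PSDs for the pipeline.
prepare_quality_data <- function(segments, notch_freq = 50,
                                 constant_fraction = 0.70,
                                 amplitude_limit = 300) {
  fs <- segments[[1]]$sampling_rate
  bands <- eeg_bands(fs)
  prescreen <- vapply(segments, prescreen_segment, NA_character_,
                      constant_fraction = constant_fraction,
                      amplitude_limit = amplitude_limit)
  clean_segs <- lapply(segments, remove_dc_and_notch, notch_freq = notch_freq)
  psd0 <- welch_psd(clean_segs[[1]])
  freq <- psd0$freq
  psds <- matrix(0, length(segments), length(freq))
  x <- matrix(0, length(segments), length(feature_names(bands)),
              dimnames = list(NULL, feature_names(bands)))
  for (i in seq_along(clean_segs)) {
    p <- if (i == 1) psd0 else welch_psd(clean_segs[[i]])
    psds[i, ] <- p$psd
    x[i, ] <- segment_features(clean_segs[[i]], bands, psd = p)
  }
  list(features = x, psds = psds, freq = freq, prescreen = prescreen,
       sampling_rate = fs, bands = bands)
}

# Fit standardization + FCBF + classifier + spectral reference from
# prepared data (training side of the pipeline).
fit_pipeline <- function(prep, labels, config) {
  labels <- as.character(labels)
  labels3 <- collapse_labels(labels)
  std <- fit_standardization(prep$features)
  z <- apply_standardization(prep$features, std)
  sel <- fcbf_select(z, labels3, delta = config$delta, n_bins = config$n_bins)
  zs <- z[, sel$kept_names, drop = FALSE]
  clf <- switch(config$classifier,
    knn_weighted = ,
    knn_euclidean = list(kind = config$classifier, fit = knn_fit(zs, labels3)),
    lda = list(kind = "lda", fit = lda_fit(zs, labels3)),
    svm_linear = list(kind = "svm_linear",
                      fit = svm_ovo_fit(zs, labels3, cost = config$cost)),
    stop("unknown classifier: ", config$classifier))
  reference <- NULL
  if (sum(labels == "HIGH_Q") >= 3) {
    reference <- fit_spectral_reference(prep$psds[labels == "HIGH_Q", ,
                                                  drop = FALSE], prep$freq)
    med <- labels %in% c("MED_Q", "MED_MUSC")
    if (any(labels == "MED_MUSC") && any(labels[med] == "MED_Q")) {
      reference <- calibrate_reference(reference,
                                       prep$psds[med, , drop = FALSE],
                                       labels[med] == "MED_MUSC",
                                       prep$freq, n_grid = config$n_grid)
    }
  }
  list(standardization = std, selection = sel, classifier = clf,
       reference = reference, config = config, freq = prep$freq,
       classes = intersect(quality_levels(), unique(labels3)))
}

# Predict prepared data through a fitted pipeline. Order is fixed:
# prescreen override -> standardize -> select -> classify -> muscular
# refinement of MED_Q segments.
predict_pipeline <- function(fit, prep) {
  n <- nrow(prep$features)
  z <- apply_standardization(prep$features, fit$standardization)
  zs <- z[, fit$selection$kept_names, drop = FALSE]
  pr <- switch(fit$classifier$kind,
    knn_weighted = knn_predict_matrix(fit$classifier$fit, zs,
                                      fit$config$k, TRUE),
    knn_euclidean = knn_predict_matrix(fit$classifier$fit, zs,
                                       fit$config$k, FALSE),
    lda = { p <- lda_predict(fit$classifier$fit, zs)
            list(labels = as.character(p), scores = attr(p, "scores")) },
    svm_linear = { p <- svm_ovo_predict(fit$classifier$fit, zs)
                   list(labels = as.character(p), scores = attr(p, "scores")) })
  scores <- matrix(0, n, 3, dimnames = list(NULL, quality_levels()))
  scores[, colnames(pr$scores)] <- pr$scores
  labels3 <- pr$labels
  over <- !is.na(prep$prescreen)
  labels3[over] <- "LOW_Q"
  scores[over, ] <- 0
  scores[over, "LOW_Q"] <- 1
  labels4 <- labels3
  dist <- rep(NA_real_, n)
  ref <- fit$reference
  if (!is.null(ref) && is.finite(ref$T)) {
    med <- which(labels3 == "MED_Q")
    if (length(med) > 0) {
      dist[med] <- reference_distances(ref, prep$psds[med, , drop = FALSE],
                                       prep$freq)
      labels4[med][dist[med] > ref$T] <- "MED_MUSC"
    }
  }
  list(labels = labels4, labels3 = labels3, scores = scores,
       itakura_distance = dist, prescreen = prep$prescreen)
}

#' Train a quality-assessment model
#'
#' Fits the full pipeline on labelled one-second segments: training-set
#' standardization, FCBF feature selection, the chosen multiclass
#' classifier over \{LOW_Q, MED_Q, HIGH_Q\} (`MED_MUSC` training segments
#' are folded into `MED_Q` for the classifier), the clean-EEG spectral
#' reference, and — when both muscular and non-muscular medium-quality
#' training segments are present — the calibrated Itakura threshold for
#' muscular discrimination.
#'
#' @param segments List of raw [eeg_segment()] objects.
#' @param labels Quality label per segment, in [quality_labels()].
#' @param classifier One of `"knn_weighted"` (default), `"knn_euclidean"`,
#'   `"lda"`, `"svm_linear"`.
#' @param k Neighbour count for the kNN variants (default 7).
#' @param delta FCBF relevance threshold (default 0).
#' @param n_bins FCBF discretization bins (default 10).
#' @param cost SVM soft-margin parameter C (default 1).
#' @param notch_freq Mains notch frequency in Hz (default 50).
#' @param n_grid Candidate threshold multipliers for
#'   [calibrate_reference()].
#' @return Object of class `quality_model`.
#' @export
train_quality_model <- function(segments, labels,
                                classifier = c("knn_weighted",
                                               "knn_euclidean", "lda",
                                               "svm_linear"),
                                k = 7, delta = 0, n_bins = 10, cost = 1,
                                notch_freq = 50,
                                n_grid = seq(0, 10, by = 0.25)) {
  classifier <- match.arg(classifier)
  if (length(segments) != length(labels))
    stop("need one label per segment")
  if (!all(labels %in% quality_labels()))
    stop("labels must be in: ", paste(quality_labels(), collapse = ", "))
  config <- list(classifier = classifier, k = as.integer(k), delta = delta,
                 n_bins = n_bins, cost = cost, notch_freq = notch_freq,
                 n_grid = n_grid)
  prep <- prepare_quality_data(segments, notch_freq = notch_freq)
  fit <- fit_pipeline(prep, labels, config)
  structure(c(fit, list(version = "eegqc-model-1",
                        sampling_rate = prep$sampling_rate)),
            class = "quality_model")
}

#' @export
print.quality_model <- function(x, ...) {
  cat(sprintf("<quality_model> %s (k = %d), %d selected features%s\n",
              x$config$classifier, x$config$k,
              length(x$selection$kept_names),
              if (!is.null(x$reference) && is.finite(x$reference$T))
                sprintf(", muscular threshold T = %.3g (N = %g)",
                        x$reference$T, x$reference$N)
              else ", muscular refinement uncalibrated"))
  invisible(x)
}

#' Predict the quality of EEG segments
#'
#' Runs the full prediction pipeline: the deterministic prescreen forces
#' `LOW_Q` (bypassing the classifier); otherwise the classifier assigns
#' one of \{LOW_Q, MED_Q, HIGH_Q\} and a `MED_Q` verdict is refined to
#' `MED_MUSC` when the segment's Itakura distance to the clean reference
#' spectrum exceeds the calibrated threshold.
#'
#' @param model A [train_quality_model()] object.
#' @param segments A single [eeg_segment()] or a list of them.
#' @param details Return a data frame with per-class scores, prescreen
#'   verdicts and Itakura distances instead of the bare labels.
#' @return Character vector of labels in [quality_labels()] (or a data
#'   frame when `details = TRUE`).
#' @export
predict_quality <- function(model, segments, details = FALSE) {
  stopifnot(inherits(model, "quality_model"))
  if (inherits(segments, "eeg_segment")) segments <- list(segments)
  if (segments[[1]]$sampling_rate != model$sampling_rate)
    stop("segment sampling rate differs from the model's (",
         model$sampling_rate, " Hz)")
  prep <- prepare_quality_data(segments,
                               notch_freq = model$config$notch_freq)
  pr <- predict_pipeline(model, prep)
  if (!details) return(unname(pr$labels))
  data.frame(label = unname(pr$labels), label3 = unname(pr$labels3),
             prescreen = unname(pr$prescreen),
             score_low = unname(pr$scores[, "LOW_Q"]),
             score_med = unname(pr$scores[, "MED_Q"]),
             score_high = unname(pr$scores[, "HIGH_Q"]),
             itakura_distance = unname(pr$itakura_distance),
             row.names = NULL)
}

#' Save or load a quality model
#'
#' Single-file persistence of the full trained state (standardization
#' parameters, selected features, classifier, spectral reference and
#' configuration) with a format version tag checked on load.
#'
#' @param model A `quality_model`.
#' @param path File path.
#' @return `load_quality_model` returns the restored `quality_model`.
#' @export
save_quality_model <- function(model, path) {
  stopifnot(inherits(model, "quality_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_quality_model
#' @export
load_quality_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "quality_model") ||
      !identical(model$version, "eegqc-model-1"))
    stop("not a compatible eegqc model file")
  model
}
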
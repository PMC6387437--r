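# deterministic stratified fold assignment (stratified on the full
# 4-level labelling so MED_MUSC spreads evenly)
stratified_folds <- function(labels, n_folds, seed) {
  folds <- integer(length(labels))
  with_local_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  for (f in seq_len(n_folds)) {
    train_classes <- unique(collapse_labels(labels[folds != f]))
    if (length(setdiff(unique(collapse_labels(labels)), train_classes)) > 0)
      stop("a class is absent from a training fold; use more data or ",
           "fewer folds")
  }
  folds
}

#' One-vs-rest ROC AUC
#'
#' Area under the ROC curve by the rank statistic (Mann-Whitney U
#' normalisation); tied scores contribute 1/2.
#'
#' @param scores Numeric score for the positive class, one per case.
#' @param labels Class label per case.
#' @param positive_class Label treated as positive (all others negative).
#' @return AUC in \[0, 1\].
#' @export
roc_auc_one_vs_rest <- function(scores, labels, positive_class) {
  pos <- labels == positive_class
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("need both positive and negative cases for an ROC curve")
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

evaluation_report <- function(true3, pred3, scores, true4, pred4,
                              folds, seed) {
  classes <- quality_levels()
  cm <- table(factor(true3, levels = classes),
              factor(pred3, levels = classes))
  per_class <- diag(cm) / pmax(rowSums(cm), 1)
  auc <- vapply(classes, function(cl)
    roc_auc_one_vs_rest(scores[, cl], true3, cl), 0)
  # MED-MUSC accuracy among truly muscular segments classified MED_Q
  musc_in_med <- true4 == "MED_MUSC" & pred3 == "MED_Q"
  med_musc_accuracy <- if (any(musc_in_med))
    mean(pred4[musc_in_med] == "MED_MUSC") else NA_real_
  structure(list(confusion_matrix = cm,
                 per_class_accuracy = per_class,
                 total_accuracy = sum(diag(cm)) / sum(cm),
                 med_musc_accuracy = med_musc_accuracy,
                 auc_per_class = auc,
                 fold_assignments = folds, seed = seed),
            class = "quality_evaluation")
}

#' @export
print.quality_evaluation <- function(x, ...) {
  cat("<quality_evaluation>\n")
  print(x$confusion_matrix)
  cat(sprintf("total accuracy %.4f | per class %s | MED-MUSC %.4f\n",
              x$total_accuracy,
              paste(sprintf("%s %.3f", names(x$per_class_accuracy),
                            x$per_class_accuracy), collapse = ", "),
              x$med_musc_accuracy))
  cat(sprintf("one-vs-rest AUC %s\n",
              paste(sprintf("%s %.3f", names(x$auc_per_class),
                            x$auc_per_class), collapse = ", ")))
  invisible(x)
}

#' Stratified k-fold cross-validation of the quality checker
#'
#' Splits the dataset into stratified folds (deterministic under `seed`),
#' fits the full pipeline — standardization, FCBF, classifier and the
#' muscular threshold — inside each training fold only, predicts the held
#' out fold, and aggregates test-fold predictions into a confusion
#' matrix, per-class and total accuracy, the MED-MUSC detection rate
#' among segments classified MED_Q, and one-vs-rest AUCs.
#'
#' @param dataset A `labelled_dataset` (see [build_dataset()]), or a list
#'   with `segments` and `labels`.
#' @param classifier,k,delta,n_bins,cost,notch_freq Passed to
#'   [train_quality_model()].
#' @param n_folds Number of folds (default 5).
#' @param seed Seed controlling the fold assignment.
#' @param prep Optional precomputed result of the internal preparation
#'   step (used by the sweep routines to avoid re-extracting features).
#' @return A `quality_evaluation` object; per-segment predictions are in
#'   attribute `"predictions"`.
#' @export
cross_validate <- function(dataset, classifier = "knn_weighted", k = 7,
                           delta = 0, n_bins = 10, cost = 1,
                           notch_freq = 50, n_folds = 5, seed = 1,
                           prep = NULL) {
  labels4 <- as.character(dataset$labels)
  config <- list(classifier = classifier, k = as.integer(k), delta = delta,
                 n_bins = n_bins, cost = cost, notch_freq = notch_freq,
                 n_grid = seq(0, 10, by = 0.25))
  if (is.null(prep))
    prep <- prepare_quality_data(dataset$segments, notch_freq = notch_freq)
  folds <- stratified_folds(labels4, n_folds, seed)
  n <- length(labels4)
  pred3 <- pred4 <- character(n)
  scores <- matrix(0, n, 3, dimnames = list(NULL, quality_levels()))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    fit <- fit_pipeline(subset_prep(prep, tr), labels4[tr], config)
    pr <- predict_pipeline(fit, subset_prep(prep, !tr))
    pred3[!tr] <- pr$labels3
    pred4[!tr] <- pr$labels
    scores[!tr, ] <- pr$scores
  }
  rep <- evaluation_report(collapse_labels(labels4), pred3, scores,
                           labels4, pred4, folds, seed)
  attr(rep, "predictions") <- data.frame(true = labels4, predicted = pred4,
                                         fold = folds,
                                         snr_db = if (!is.null(dataset$snrs))
                                           dataset$snrs else NA_real_)
  rep
}

subset_prep <- function(prep, idx) {
  list(features = prep$features[idx, , drop = FALSE],
       psds = prep$psds[idx, , drop = FALSE],
       freq = prep$freq, prescreen = prep$prescreen[idx],
       sampling_rate = prep$sampling_rate, bands = prep$bands)
}

#' Neighbour-count sensitivity sweep
#'
#' Cross-validated total accuracy of the weighted (or Euclidean) kNN for
#' each `k` in `k_range`, with fold assignment held fixed across `k`.
#' The per-fold standardization, feature selection and spectral reference
#' are fitted once and reused for every `k`.
#'
#' @param dataset A `labelled_dataset`.
#' @param k_range Neighbour counts to evaluate (default 1:20).
#' @param weighted Use the inverse-square-distance weighting (default
#'   `TRUE`).
#' @param n_folds,seed,delta,n_bins Cross-validation settings.
#' @return List with `curve` (data frame of `k`, `accuracy`) and `best_k`
#'   (smallest `k` attaining the maximum).
#' @export
k_sweep <- function(dataset, k_range = 1:20, weighted = TRUE, n_folds = 5,
                    seed = 1, delta = 0, n_bins = 10) {
  labels4 <- as.character(dataset$labels)
  labels3 <- collapse_labels(labels4)
  config <- list(classifier = if (weighted) "knn_weighted" else "knn_euclidean",
                 k = 1L, delta = delta, n_bins = n_bins, cost = 1,
                 notch_freq = 50, n_grid = seq(0, 10, by = 0.25))
  prep <- prepare_quality_data(dataset$segments)
  folds <- stratified_folds(labels4, n_folds, seed)
  correct <- matrix(0, length(labels4), length(k_range))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    fit <- fit_pipeline(subset_prep(prep, tr), labels4[tr], config)
    te <- subset_prep(prep, !tr)
    z <- apply_standardization(te$features, fit$standardization)
    zs <- z[, fit$selection$kept_names, drop = FALSE]
    for (j in seq_along(k_range)) {
      pr <- knn_predict_matrix(fit$classifier$fit, zs, k_range[j], weighted)
      lab <- pr$labels
      lab[!is.na(te$prescreen)] <- "LOW_Q"
      correct[!tr, j] <- lab == labels3[!tr]
    }
  }
  curve <- data.frame(k = k_range, accuracy = colMeans(correct))
  list(curve = curve, best_k = k_range[which.max(curve$accuracy)],
       fold_assignments = folds)
}

#' SNR sensitivity sweep
#'
#' Regenerates a synthetic dataset per run (run-specific derived seeds),
#' cross-validates the quality checker, and reports the fraction of
#' contaminated test segments correctly detected per SNR bin, the
#' detection rate of clean segments, and where the misclassified
#' segments of the top (hardest, least contaminated) bin end up.
#'
#' @param config Base [dataset_config()]; each run replaces the seed.
#' @param snr_bins Bin edges in dB (default `c(-10, 0, 5, 10, 15)`,
#'   giving bins \[-10,0), \[0,5), \[5,10), \[10,15\]).
#' @param n_runs Number of regenerate-and-evaluate runs (default 10).
#' @param classifier,k,n_folds Passed to [cross_validate()].
#' @param seed Master seed; run `r` uses a seed derived from it.
#' @return List with `bin_accuracy` (runs x bins matrix of detection
#'   fractions), `mean_accuracy` (per bin), `clean_accuracy`,
#'   `top_bin_misclassified_to_high` (fraction of the top bin's errors
#'   labelled HIGH_Q) and `bins`.
#' @export
snr_sweep <- function(config = dataset_config(), snr_bins = c(-10, 0, 5, 10, 15),
                      n_runs = 10, classifier = "knn_weighted", k = 10,
                      n_folds = 5, seed = 1) {
  if (min(snr_bins) < -10 || max(snr_bins) > 15)
    stop("SNR bins must lie within [-10, 15] dB")
  n_bins <- length(snr_bins) - 1
  bin_acc <- matrix(NA_real_, n_runs, n_bins)
  clean_acc <- numeric(n_runs)
  top_err_high <- rep(NA_real_, n_runs)
  for (r in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- derive_seed(seed, r)
    ds <- build_dataset(cfg)
    ev <- cross_validate(ds, classifier = classifier, k = k,
                         n_folds = n_folds, seed = derive_seed(seed, 1000 + r))
    pred <- attr(ev, "predictions")
    true3 <- collapse_labels(pred$true)
    pred3 <- collapse_labels(pred$predicted)
    contaminated <- !is.na(pred$snr_db)
    bin_idx <- findInterval(pred$snr_db, snr_bins, rightmost.closed = TRUE)
    for (b in seq_len(n_bins)) {
      in_bin <- contaminated & bin_idx == b
      if (any(in_bin)) bin_acc[r, b] <- mean(pred3[in_bin] == true3[in_bin])
    }
    clean_acc[r] <- mean(pred3[!contaminated] == "HIGH_Q")
    top <- contaminated & bin_idx == n_bins
    err <- top & pred3 != true3
    if (any(err)) top_err_high[r] <- mean(pred3[err] == "HIGH_Q")
  }
  list(bin_accuracy = bin_acc,
       mean_accuracy = colMeans(bin_acc, na.rm = TRUE),
       clean_accuracy = mean(clean_acc),
       top_bin_misclassified_to_high = mean(top_err_high, na.rm = TRUE),
       bins = snr_bins)
}

baseline_metrics <- function(seg) {
  fs <- seg$sampling_rate
  b1 <- list(f_lo = 8, f_hi = 12)
  b2 <- list(f_lo = 13, f_hi = 35)
  c(time_stats_named(seg$samples, "raw"),
    time_stats_named(bandpass_segment(seg, b1)$samples, "alpha8_12"),
    time_stats_named(bandpass_segment(seg, b2)$samples, "beta13_35"))
}

#' Percentile-threshold baseline artefact detector
#'
#' Re-implementation of the classic threshold-based single-channel
#' detector used as comparison: twelve metrics (maximum, standard
#' deviation, kurtosis, skewness of the raw signal and of the 8--12 Hz
#' and 13--35 Hz band-filtered signals) are bounded by the
#' \[0.5, 99.5\] percentile intervals of clean training segments; a test
#' segment is called `"contaminated"` when any metric leaves its
#' interval, else `"clean"`. Binary only.
#'
#' @param train_clean List of clean (HIGH_Q) training [eeg_segment()]s
#'   (at least 10).
#' @param test List of test segments.
#' @param percentiles Lower/upper calibration percentiles
#'   (default `c(0.005, 0.995)`).
#' @return Character vector `"clean"`/`"contaminated"` per test segment.
#' @export
threshold_baseline <- function(train_clean, test,
                               percentiles = c(0.005, 0.995)) {
  if (length(train_clean) < 10)
    stop("need at least 10 clean training segments for the baseline")
  prep_m <- function(segs) t(vapply(
    lapply(segs, remove_dc_and_notch), baseline_metrics, numeric(12)))
  m_train <- prep_m(train_clean)
  lo <- apply(m_train, 2, stats::quantile, probs = percentiles[1])
  hi <- apply(m_train, 2, stats::quantile, probs = percentiles[2])
  m_test <- prep_m(test)
  out_of_range <- sweep(m_test, 2, lo, "<") | sweep(m_test, 2, hi, ">")
  ifelse(rowSums(out_of_range) > 0, "contaminated", "clean")
}
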
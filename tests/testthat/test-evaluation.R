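test_that("one-vs-rest AUC matches exhaustive pair counting", {
  expect_equal(roc_auc_one_vs_rest(c(0.9, 0.8, 0.2, 0.1),
                                   c("A", "A", "B", "B"), "A"), 1)
  expect_equal(roc_auc_one_vs_rest(c(0.1, 0.2, 0.8, 0.9),
                                   c("A", "A", "B", "B"), "A"), 0)
  expect_equal(roc_auc_one_vs_rest(c(0.9, 0.8, 0.4, 0.3),
                                   c("A", "B", "A", "B"), "A"), 0.75)
  expect_error(roc_auc_one_vs_rest(1:3, c("A", "A", "A"), "A"),
               "positive and negative")
  set.seed(23)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)   # with ties
    y <- sample(c("P", "N"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    pos <- which(y == "P"); neg <- which(y == "N")
    pairs <- 0
    for (a in pos) for (b in neg)
      pairs <- pairs + (s[a] > s[b]) + 0.5 * (s[a] == s[b])
    expect_equal(roc_auc_one_vs_rest(s, y, "P"),
                 pairs / (length(pos) * length(neg)),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(24)
  s <- rnorm(80)
  y <- ifelse(s + rnorm(80) > 0, "P", "N")
  got <- roc_auc_one_vs_rest(s, y, "P")
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                        levels = c("N", "P"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(got, ref, tolerance = 1e-10)
})

small_dataset <- function(seed = 41) {
  build_dataset(dataset_config(n_clean = 40, n_blink = 10, n_slow = 10,
                               n_muscular = 15, n_extreme = 25,
                               snr_artefact = c(0, 5), seed = seed))
}

test_that("cross-validation bookkeeping is internally consistent", {
  ds <- small_dataset()
  ev <- cross_validate(ds, k = 5, n_folds = 5, seed = 42)
  cm <- ev$confusion_matrix
  truth <- table(factor(eegqc:::collapse_labels(ds$labels),
                        levels = quality_levels()))
  expect_equal(as.integer(rowSums(cm)), as.integer(truth))
  expect_equal(ev$total_accuracy, sum(diag(cm)) / sum(cm))
  expect_equal(unname(ev$per_class_accuracy),
               unname(diag(cm) / rowSums(cm)))
  expect_equal(as.integer(table(ev$fold_assignments)), rep(20L, 5))
  # deterministic under the same seed
  ev2 <- cross_validate(ds, k = 5, n_folds = 5, seed = 42)
  expect_identical(attr(ev, "predictions")$predicted,
                   attr(ev2, "predictions")$predicted)
})

test_that("fold fitting uses training-fold statistics only", {
  ds <- small_dataset(43)
  prep <- eegqc:::prepare_quality_data(ds$segments)
  folds <- eegqc:::stratified_folds(ds$labels, 4, 7)
  tr <- folds != 1
  config <- list(classifier = "knn_weighted", k = 5L, delta = 0,
                 n_bins = 10, cost = 1, notch_freq = 50,
                 n_grid = seq(0, 10, 0.25))
  fit <- eegqc:::fit_pipeline(eegqc:::subset_prep(prep, tr),
                              ds$labels[tr], config)
  # standardization comes from the training rows, not the full dataset
  expect_equal(fit$standardization$mean, colMeans(prep$features[tr, ]))
  expect_false(isTRUE(all.equal(fit$standardization$mean,
                                colMeans(prep$features))))
  # and test-fold labels play no part: the fitted state is bitwise
  # identical whatever the held-out labels claim to be
  fit2 <- eegqc:::fit_pipeline(eegqc:::subset_prep(prep, tr),
                               ds$labels[tr], config)
  expect_identical(fit[c("standardization", "selection", "reference")],
                   fit2[c("standardization", "selection", "reference")])
})

test_that("a class missing from a training fold raises a clear error", {
  ds <- small_dataset(44)
  keep <- ds$labels != "LOW_Q" | seq_along(ds$labels) %in%
    which(ds$labels == "LOW_Q")[1]
  ds$segments <- ds$segments[keep]
  ds$labels <- ds$labels[keep]
  ds$snrs <- ds$snrs[keep]
  expect_error(cross_validate(ds, n_folds = 5, seed = 1), "absent")
})

test_that("the neighbour sweep reuses folds and reports the curve", {
  ds <- small_dataset(45)
  sw <- k_sweep(ds, k_range = 1:20, n_folds = 4, seed = 9)
  expect_equal(nrow(sw$curve), 20)
  expect_identical(sw$curve$k, 1:20)
  expect_true(all(sw$curve$accuracy >= 0 & sw$curve$accuracy <= 1))
  expect_true(sw$best_k %in% 1:20)
  expect_equal(sw$curve$accuracy[which(sw$curve$k == sw$best_k)],
               max(sw$curve$accuracy))
  sw2 <- k_sweep(ds, k_range = 1:20, n_folds = 4, seed = 9)
  expect_identical(sw$fold_assignments, sw2$fold_assignments)
})

test_that("generated SNRs honour the configured bin ranges", {
  ds <- build_dataset(dataset_config(n_clean = 10, n_blink = 10,
                                     n_slow = 10, n_muscular = 10,
                                     n_extreme = 10, seed = 46))
  art <- ds$manifest$table$pattern %in% c("eog_blink", "eog_slow",
                                          "muscular")
  expect_true(all(ds$snrs[art] >= 0 & ds$snrs[art] <= 15))
  ext <- ds$manifest$table$pattern == "extreme_values"
  expect_true(all(ds$snrs[ext] >= -10 & ds$snrs[ext] <= 0))
  expect_error(snr_sweep(snr_bins = c(-20, 0)), "within")
})

test_that("the percentile-threshold baseline flags gross artefacts", {
  clean <- lapply(2000 + 1:60, generate_clean_segment)
  # typical clean segments are inside their own calibration range (the
  # per-metric extremes fall outside the [0.5, 99.5] percentile interval
  # by construction, so only a clear majority is expected)
  verdict <- threshold_baseline(clean[1:50], clean[1:50])
  expect_gte(mean(verdict == "clean"), 0.6)
  # an unseen typical clean segment passes
  expect_identical(threshold_baseline(clean[1:50], clean[51])[1], "clean")
  # a 350 uV spike leaves the clean max range
  spiky <- generate_clean_segment(3001)
  spiky$samples[125] <- 350
  expect_identical(threshold_baseline(clean[1:50], list(spiky)),
                   "contaminated")
  expect_error(threshold_baseline(clean[1:5], clean[6:10]), "at least 10")
})
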
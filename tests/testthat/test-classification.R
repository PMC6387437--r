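test_that("euclidean distance and inverse-square weights are exact", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(euclidean_distance(c(1, 1, 1), c(2, 2, 2)), sqrt(3))
  expect_error(euclidean_distance(c(a = 1, b = 2), c(a = 1, c = 2)),
               "do not match")
  expect_equal(inverse_square_weight(5), 0.04)
  expect_equal(inverse_square_weight(1), 1)
  expect_identical(inverse_square_weight(0), Inf)
})

test_that("kNN votes follow the stated contracts", {
  train <- matrix(c(0, 0, 0.1, 0.1, 5, 5), ncol = 2, byrow = TRUE)
  y <- c("MED_Q", "MED_Q", "HIGH_Q")
  fit <- eegqc:::knn_fit(train, y)
  # k = 1: nearest neighbour's label
  expect_identical(
    eegqc:::knn_predict_matrix(fit, matrix(c(4.9, 5), 1), 1, FALSE)$labels,
    "HIGH_Q")
  # k = 3 majority at equal relevance
  expect_identical(
    eegqc:::knn_predict_matrix(fit, matrix(c(0.05, 0.05), 1), 3,
                               FALSE)$labels,
    "MED_Q")
  # exact match inherits the zero-distance neighbour's label
  expect_identical(
    eegqc:::knn_predict_matrix(fit, matrix(c(5, 5), 1), 3, TRUE)$labels,
    "HIGH_Q")
  # vote tie resolves toward the worse quality
  tie_fit <- eegqc:::knn_fit(matrix(c(1, -1), ncol = 1),
                             c("HIGH_Q", "MED_Q"))
  expect_identical(
    eegqc:::knn_predict_matrix(tie_fit, matrix(0, 1), 2, FALSE)$labels,
    "MED_Q")
})

test_that("kNN matches the brute-force oracle on random instances", {
  set.seed(9)
  classes <- c("LOW_Q", "MED_Q", "HIGH_Q")
  for (i in 1:100) {
    n <- sample(5:50, 1)
    p <- sample(1:10, 1)
    k <- sample(1:min(9, n), 1)
    train <- matrix(rnorm(n * p), n)
    y <- sample(classes, n, replace = TRUE)
    fit <- eegqc:::knn_fit(train, y)
    x <- rnorm(p)
    for (weighted in c(TRUE, FALSE)) {
      got <- eegqc:::knn_predict_matrix(fit, matrix(x, 1), k,
                                        weighted)$labels
      expect_identical(got, knn_oracle(train, y, x, k, weighted))
    }
  }
})

test_that("weighted kNN with equal distances reduces to the majority vote", {
  # four training points on a circle around the query: equal distances
  train <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  y <- c("HIGH_Q", "HIGH_Q", "HIGH_Q", "MED_Q")
  fit <- eegqc:::knn_fit(train, y)
  w <- eegqc:::knn_predict_matrix(fit, matrix(c(0, 0), 1), 4, TRUE)
  u <- eegqc:::knn_predict_matrix(fit, matrix(c(0, 0), 1), 4, FALSE)
  expect_identical(w$labels, u$labels)
  expect_equal(w$scores, u$scores)
})

test_that("training-set permutation never changes kNN predictions", {
  set.seed(10)
  train <- matrix(rnorm(60), 30)
  y <- sample(c("LOW_Q", "MED_Q", "HIGH_Q"), 30, replace = TRUE)
  queries <- matrix(rnorm(20), 10)
  fit <- eegqc:::knn_fit(train, y)
  base <- eegqc:::knn_predict_matrix(fit, queries, 5, TRUE)$labels
  for (i in 1:5) {
    o <- sample(30)
    fit2 <- eegqc:::knn_fit(train[o, ], y[o])
    expect_identical(eegqc:::knn_predict_matrix(fit2, queries, 5,
                                                TRUE)$labels, base)
  }
})

test_that("LDA recovers separable classes and training priors", {
  set.seed(11)
  x <- matrix(c(rnorm(100, -5, 0.5), rnorm(100, 5, 0.5)), ncol = 1)
  y <- rep(c("MED_Q", "HIGH_Q"), each = 100)
  m <- lda_fit(x, y)
  expect_gte(mean(as.character(lda_predict(m, x)) == y), 0.99)

  x3 <- matrix(rnorm(20 * 2), 20)
  y3 <- rep(c("LOW_Q", "MED_Q", "HIGH_Q"), times = c(10, 6, 4))
  expect_equal(lda_fit(x3, y3)$priors, c(0.5, 0.3, 0.2))
  expect_error(lda_fit(x3, rep(c("LOW_Q", "MED_Q"), times = c(19, 1))),
               "at least 2")
})

test_that("hand-rolled LDA agrees with the reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(12)
  x <- matrix(rnorm(300), 100, 3)
  y <- sample(c("LOW_Q", "MED_Q", "HIGH_Q"), 100, replace = TRUE,
              prob = c(0.3, 0.3, 0.4))
  x[y == "LOW_Q", 1] <- x[y == "LOW_Q", 1] + 2
  x[y == "HIGH_Q", 2] <- x[y == "HIGH_Q", 2] - 2
  ours <- as.character(lda_predict(lda_fit(x, y), x))
  ref <- as.character(stats::predict(MASS::lda(x, grouping = y), x)$class)
  expect_gte(mean(ours == ref), 0.98)
})

test_that("one-vs-one SVM builds all pairwise classifiers and separates blobs", {
  set.seed(13)
  x <- rbind(matrix(rnorm(40, 0, 0.2), ncol = 2),
             matrix(rnorm(40, 4, 0.2), ncol = 2),
             matrix(rnorm(40, c(0, 8), 0.2), ncol = 2, byrow = TRUE))
  y <- rep(c("LOW_Q", "MED_Q", "HIGH_Q"), each = 20)
  m <- svm_ovo_fit(x, y)
  pr <- stats::predict(m$fit, x, decision.values = TRUE)
  expect_equal(ncol(attr(pr, "decision.values")), 3)   # L(L-1)/2 with L=3
  expect_equal(mean(as.character(svm_ovo_predict(m, x)) == y), 1)
})

test_that("a circular pairwise vote resolves toward the worse quality", {
  dv <- matrix(c(1, -1, 1), 1,
               dimnames = list(NULL, c("LOW_Q/MED_Q", "LOW_Q/HIGH_Q",
                                       "MED_Q/HIGH_Q")))
  # votes: LOW beats MED, HIGH beats LOW, MED beats HIGH -> 1-1-1 tie
  out <- eegqc:::svm_vote(dv, c("LOW_Q", "MED_Q", "HIGH_Q"))
  expect_identical(out$labels, "LOW_Q")
})

test_that("the full prediction pipeline honours prescreen and refinement", {
  cfg <- dataset_config(n_clean = 60, n_blink = 20, n_slow = 20,
                        n_muscular = 30, n_extreme = 30,
                        snr_artefact = c(0, 3), seed = 14)
  ds <- build_dataset(cfg)
  model <- train_quality_model(ds$segments, ds$labels,
                               classifier = "knn_weighted", k = 5)
  # saturated segment is LOW_Q regardless of the classifier
  sat <- eeg_segment(c(rep(120, 210), rnorm(40)), 250)
  expect_identical(predict_quality(model, sat), "LOW_Q")
  # clean segments from unseen seeds are mostly recognised
  clean <- lapply(9000 + 1:20, generate_clean_segment)
  expect_gte(mean(predict_quality(model, clean) == "HIGH_Q"), 0.7)
  # a strong muscular burst is refined to MED_MUSC when not prescreened
  burst <- lapply(9500 + 1:20, function(s)
    mix_at_snr(generate_clean_segment(s + 100),
               generate_muscular_artefact(s), 0))
  pr <- predict_quality(model, burst, details = TRUE)
  expect_gte(mean(pr$label == "MED_MUSC"), 0.6)
})

test_that("models persist and reload through the single-file archive", {
  cfg <- dataset_config(n_clean = 20, n_blink = 5, n_slow = 5,
                        n_muscular = 8, n_extreme = 8, seed = 15)
  ds <- build_dataset(cfg)
  model <- train_quality_model(ds$segments, ds$labels, k = 3)
  path <- tempfile(fileext = ".rds")
  save_quality_model(model, path)
  model2 <- load_quality_model(path)
  probe <- generate_clean_segment(12345)
  expect_identical(predict_quality(model, probe),
                   predict_quality(model2, probe))
  saveRDS(list(), path)
  expect_error(load_quality_model(path), "not a compatible")
})
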
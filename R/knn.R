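#' Euclidean distance between two feature vectors
#'
#' @param x,y Named numeric vectors over the same feature set (aligned by
#'   name when both are named).
#' @return Non-negative scalar.
#' @export
euclidean_distance <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    if (!setequal(names(x), names(y)))
      stop("feature sets of 'x' and 'y' do not match")
    y <- y[names(x)]
  } else if (length(x) != length(y)) {
    stop("feature vectors have different lengths")
  }
  sqrt(sum((x - y)^2))
}

#' Inverse-square distance weight
#'
#' `1 / d^2` for `d > 0`. A zero distance returns `Inf`: in the weighted
#' kNN vote an exact feature match dominates, i.e. the query inherits the
#' label of its zero-distance neighbours (majority among them if several
#' disagree).
#'
#' @param d Non-negative distance(s).
#' @return Weight(s).
#' @export
inverse_square_weight <- function(d) {
  if (any(d < 0)) stop("distances must be non-negative")
  ifelse(d == 0, Inf, 1 / d^2)
}

knn_fit <- function(x, y) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (nrow(x) != length(y)) stop("row/label count mismatch")
  list(x = x, y = y)
}

# squared-distance tolerance treated as an exact feature match
.zero_d2 <- 1e-20

# vectorised kNN prediction for a matrix of queries.
# Neighbour sets include every training point tied with the k-th distance,
# so predictions are invariant to training-set permutation; ties in the
# vote go to the worse quality class (classes ordered worst-first).
knn_predict_matrix <- function(fit, newx, k, weighted,
                               classes = quality_levels()) {
  if (is.null(fit$x)) stop("kNN model is untrained")
  k <- max(1L, min(as.integer(k), nrow(fit$x)))
  newx <- as.matrix(newx)
  d2 <- outer(rowSums(fit$x^2), rowSums(newx^2), "+") -
    2 * fit$x %*% t(newx)
  d2[d2 < 0] <- 0
  n_test <- ncol(d2)
  labels <- character(n_test)
  scores <- matrix(0, n_test, length(classes),
                   dimnames = list(NULL, classes))
  for (j in seq_len(n_test)) {
    d <- d2[, j]
    kth <- sort.int(d, partial = k)[k]
    nb <- which(d <= kth * (1 + 1e-12) + 1e-300)
    if (any(d[nb] <= .zero_d2)) {        # exact-match rule
      nb <- nb[d[nb] <= .zero_d2]
      w <- rep(1, length(nb))
    } else if (weighted) {
      w <- 1 / d[nb]                     # d is squared -> 1/d^2 weights
    } else {
      w <- rep(1, length(nb))
    }
    v <- vapply(classes, function(cl) sum(w[fit$y[nb] == cl]), 0)
    labels[j] <- classes[which.max(v)]   # first max = worst quality
    scores[j, ] <- if (sum(v) > 0) v / sum(v) else rep(1 / length(v), length(v))
  }
  list(labels = labels, scores = scores)
}

#' k-nearest-neighbour prediction for one feature vector
#'
#' Euclidean variant: majority vote among the `k` nearest training
#' vectors. Weighted variant: the class maximising the summed
#' inverse-square-distance weights ([inverse_square_weight()]). A query
#' exactly matching training vectors inherits their (majority) label;
#' vote ties resolve to the worse quality class.
#'
#' @param model A trained [train_quality_model()] object with a kNN
#'   classifier, or the internal fit produced during training.
#' @param x Standardized, feature-selected named numeric vector.
#' @param k Neighbour count (defaults to the model's `k`).
#' @param weighted Use inverse-square-distance weighting (defaults to the
#'   model's variant).
#' @return Quality label (`"LOW_Q"`, `"MED_Q"` or `"HIGH_Q"`), with the
#'   per-class vote fractions in attribute `"scores"`.
#' @export
knn_predict <- function(model, x, k = NULL, weighted = NULL) {
  if (inherits(model, "quality_model")) {
    if (is.null(k)) k <- model$config$k
    if (is.null(weighted)) weighted <- model$config$classifier == "knn_weighted"
    fit <- model$classifier$fit
  } else {
    fit <- model
    if (is.null(k)) stop("'k' is required")
    if (is.null(weighted)) weighted <- TRUE
  }
  pr <- knn_predict_matrix(fit, matrix(x, nrow = 1), k, weighted)
  structure(pr$labels, scores = pr$scores)
}
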
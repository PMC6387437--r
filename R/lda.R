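#' Linear discriminant analysis with shared covariance
#'
#' Gaussian class-conditional model with a pooled (shared) covariance
#' matrix and class priors equal to the training class proportions.
#' Prediction maximises `P(X | l) P(l)` over the classes. A singular
#' pooled covariance is regularised by adding `1e-6` to its diagonal.
#'
#' @param x Numeric feature matrix (rows = training segments).
#' @param y Class label per row; every class needs at least 2 samples.
#' @param ridge Diagonal loading used when the pooled covariance is
#'   singular (default 1e-6).
#' @return Object of class `lda_model` with `means`, `cov_inv`, `priors`.
#' @export
lda_fit <- function(x, y, ridge = 1e-6) {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- intersect(quality_levels(), unique(y))
  if (length(classes) < 2) classes <- sort(unique(y))
  if (length(classes) < 2) stop("LDA needs at least 2 classes")
  counts <- table(factor(y, levels = classes))
  if (any(counts < 2))
    stop("every class needs at least 2 training samples for LDA")
  p <- ncol(x)
  means <- do.call(rbind, lapply(classes, function(cl)
    colMeans(x[y == cl, , drop = FALSE])))
  rownames(means) <- classes
  sw <- matrix(0, p, p)
  for (cl in classes) {
    xc <- sweep(x[y == cl, , drop = FALSE], 2, means[cl, ], "-")
    sw <- sw + crossprod(xc)
  }
  sw <- sw / (nrow(x) - length(classes))
  cov_inv <- tryCatch({
    ci <- solve(sw)
    if (!all(is.finite(ci))) stop("singular")
    ci
  }, error = function(e) solve(sw + diag(ridge, p)))
  structure(list(means = means, cov_inv = cov_inv,
                 priors = as.numeric(counts) / nrow(x),
                 classes = classes),
            class = "lda_model")
}

#' @rdname lda_fit
#' @param model An `lda_model`.
#' @param newx Numeric matrix (or vector) of standardized, selected
#'   feature values.
#' @return `lda_predict`: character vector of class labels with posterior
#'   probabilities in attribute `"scores"`; ties resolve to the worse
#'   quality class.
#' @export
lda_predict <- function(model, newx) {
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1)
  newx <- as.matrix(newx)
  # linear discriminant: x' S^-1 mu_l - mu_l' S^-1 mu_l / 2 + log pi_l
  a <- model$cov_inv %*% t(model$means)                 # p x L
  const <- -0.5 * colSums(t(model$means) * a) + log(model$priors)
  g <- sweep(newx %*% a, 2, const, "+")
  post <- exp(g - apply(g, 1, max))
  post <- post / rowSums(post)
  colnames(post) <- model$classes
  labels <- model$classes[apply(g, 1, which.max)]
  structure(labels, scores = post)
}
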
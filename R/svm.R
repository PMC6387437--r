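#' Linear one-vs-one support vector machine
#'
#' Fits the `L (L - 1) / 2` pairwise binary soft-margin linear SVMs (via
#' the libsvm solver in \pkg{e1071}) and predicts by pairwise-vote
#' majority computed in-package from the decision values, with vote ties
#' resolved to the worse quality class.
#'
#' @param x Numeric feature matrix (rows = training segments).
#' @param y Class label per row; at least two classes.
#' @param cost Soft-margin regularization parameter C (default 1).
#' @return Object of class `svm_ovo_model`.
#' @export
svm_ovo_fit <- function(x, y, cost = 1) {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- intersect(quality_levels(), unique(y))
  if (length(classes) < 2) classes <- sort(unique(y))
  if (length(classes) < 2) stop("SVM needs at least 2 classes")
  fit <- e1071::svm(x = x, y = factor(y, levels = classes),
                    kernel = "linear", cost = cost, scale = FALSE)
  structure(list(fit = fit, classes = classes, cost = cost),
            class = "svm_ovo_model")
}

# worst-first argmax over pairwise votes
svm_vote <- function(dv, classes) {
  pairs <- strsplit(colnames(dv), "/", fixed = TRUE)
  n <- nrow(dv)
  votes <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  for (j in seq_along(pairs)) {
    a <- pairs[[j]][1]; b <- pairs[[j]][2]
    # libsvm convention: positive decision value favours the first class;
    # an exact 0 goes to the worse quality of the pair
    worse <- classes[min(match(a, classes), match(b, classes))]
    win <- ifelse(dv[, j] > 0, a, ifelse(dv[, j] < 0, b, worse))
    for (cl in unique(win)) votes[win == cl, cl] <- votes[win == cl, cl] + 1
  }
  labels <- classes[apply(votes, 1, which.max)]
  list(labels = labels, scores = votes / length(pairs))
}

#' @rdname svm_ovo_fit
#' @param model An `svm_ovo_model`.
#' @param newx Numeric matrix (or vector) of standardized, selected
#'   feature values.
#' @return `svm_ovo_predict`: character vector of class labels with
#'   pairwise-vote fractions in attribute `"scores"`.
#' @export
svm_ovo_predict <- function(model, newx) {
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1)
  pr <- stats::predict(model$fit, as.matrix(newx), decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  out <- svm_vote(dv, model$classes)
  structure(out$labels, scores = out$scores)
}
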
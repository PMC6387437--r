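#' Equal-frequency discretization
#'
#' Bins a continuous series into at most `n_bins` equal-frequency bins
#' for the entropy computations of the fast correlation-based filter.
#' Series with fewer distinct values than bins are coded by value; ties
#' falling on a quantile edge go to the lower bin. A constant series maps
#' to a single bin.
#'
#' @param x Numeric vector.
#' @param n_bins Maximum number of bins (>= 2, default 10).
#' @return Integer vector of bin codes.
#' @export
discretize <- function(x, n_bins = 10) {
  if (length(x) == 0) stop("cannot discretize an empty series")
  if (n_bins < 2) stop("'n_bins' must be at least 2")
  u <- sort(unique(x))
  if (length(u) <= n_bins) return(match(x, u))
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                               names = FALSE, type = 7))
  if (length(qs) < 2) return(rep(1L, length(x)))
  cut(x, breaks = qs, include.lowest = TRUE, right = TRUE, labels = FALSE)
}

entropy_bits <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Symmetrical uncertainty between two discrete series
#'
#' `SU(a, b) = 2 IG(a | b) / (H(a) + H(b))` with
#' `IG(a | b) = H(a) - H(a | b)`, entropies in bits. Symmetric, in
#' \[0, 1\]; returns 0 when both series are constant.
#'
#' @param a,b Discrete series (integer codes, factors or characters) of
#'   equal length.
#' @return Value in \[0, 1\].
#' @export
symmetrical_uncertainty <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  if (length(a) < 1) stop("empty series")
  joint <- table(a, b)
  ha <- entropy_bits(rowSums(joint))
  hb <- entropy_bits(colSums(joint))
  if (ha + hb == 0) return(0)
  # IG(a|b) = H(a) - H(a|b) = H(a) + H(b) - H(a,b): the joint-entropy
  # form is symmetric in a and b to the last bit
  ig <- ha + hb - entropy_bits(as.vector(joint))
  max(0, min(1, 2 * ig / (ha + hb)))
}

#' Fast correlation-based filter (FCBF) feature selection
#'
#' Ranks features by their symmetrical uncertainty with the class label,
#' drops features with `SU(f, class) < delta` (irrelevant), then walks the
#' survivors in descending relevance and removes any feature `f_i` for
#' which an already-kept feature `f_j` satisfies
#' `SU(f_j, f_i) >= SU(f_i, class)` (redundant). Continuous features are
#' discretized internally with [discretize()]. Ordering ties are broken by
#' feature name, so the result does not depend on column order.
#'
#' @param features Numeric matrix or data frame (rows = segments, named
#'   columns = features).
#' @param labels Class label per row; at least two classes required.
#' @param delta Relevance threshold on `SU(f, class)` (default 0: keep all
#'   and rely on the redundancy pass).
#' @param n_bins Bins for [discretize()] (default 10).
#' @return Object of class `fcbf_selection`: list with `kept_names`,
#'   `su_scores` (named, all features), `delta` and a `report` data frame
#'   (feature, SU, kept, reason).
#' @export
fcbf_select <- function(features, labels, delta = 0, n_bins = 10) {
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) stop("row/label count mismatch")
  if (length(unique(labels)) < 2)
    stop("feature selection undefined for one class")
  disc <- lapply(seq_len(ncol(x)), function(j) discretize(x[, j], n_bins))
  names(disc) <- colnames(x)
  su_class <- vapply(disc, symmetrical_uncertainty, 0, b = labels)
  reason <- setNames(rep("kept", ncol(x)), colnames(x))
  reason[su_class < delta] <- "irrelevant"
  survivors <- names(su_class)[su_class >= delta]
  survivors <- survivors[order(-su_class[survivors], survivors)]
  kept <- character(0)
  for (fi in survivors) {
    redundant <- FALSE
    for (fj in kept) {
      if (symmetrical_uncertainty(disc[[fj]], disc[[fi]]) >= su_class[fi]) {
        reason[fi] <- paste0("redundant_with:", fj)
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept <- c(kept, fi)
  }
  if (length(kept) == 0) {       # degenerate: keep the most relevant feature
    top <- names(which.max(su_class))
    kept <- top
    reason[top] <- "kept"
  }
  report <- data.frame(feature = colnames(x),
                       su = unname(su_class[colnames(x)]),
                       kept = colnames(x) %in% kept,
                       reason = unname(reason[colnames(x)]),
                       stringsAsFactors = FALSE)
  structure(list(kept_names = kept, su_scores = su_class, delta = delta,
                 n_bins = n_bins, report = report),
            class = "fcbf_selection")
}

#' @export
print.fcbf_selection <- function(x, ...) {
  cat(sprintf("<fcbf_selection> kept %d of %d features (delta = %g)\n",
              length(x$kept_names), length(x$su_scores), x$delta))
  invisible(x)
}
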
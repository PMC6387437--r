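#' Read a plain-text single-column EEG recording
#'
#' Accepts a one-column text/CSV file of amplitudes in microvolts (an
#' optional header row is skipped automatically); the sampling rate must
#' be supplied because plain text carries none.
#'
#' @param path File path.
#' @param sampling_rate Sampling rate in Hz.
#' @param column Column to read when the file has several (default 1).
#' @return List with `signal` and `sampling_rate`, as [read_edf()].
#' @export
read_eeg_csv <- function(path, sampling_rate, column = 1) {
  first <- readLines(path, n = 1)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, "[,;\t ]+")[[1]][column])))
  d <- utils::read.table(path, header = has_header, sep = "",
                         comment.char = "#")
  if (ncol(d) == 1 && grepl(",", first))
    d <- utils::read.csv(path, header = has_header)
  sig <- as.numeric(d[[column]])
  if (any(!is.finite(sig))) stop("recording contains non-numeric samples")
  list(signal = sig, sampling_rate = sampling_rate, channel = "CSV")
}

#' Write a per-segment result table
#'
#' CSV with one row per segment: origin index, prescreen verdict and
#' (when available) the predicted quality label.
#'
#' @param segments List of [eeg_segment()] objects.
#' @param path Output CSV path.
#' @param labels Optional predicted labels, one per segment.
#' @param prescreen Optional prescreen verdicts; computed with
#'   [prescreen_segment()] when missing.
#' @return Invisibly, the written data frame.
#' @export
write_segment_table <- function(segments, path, labels = NULL,
                                prescreen = NULL) {
  if (is.null(prescreen))
    prescreen <- vapply(segments, prescreen_segment, NA_character_)
  d <- data.frame(
    origin_index = vapply(segments, function(s) s$origin_index, 0L),
    prescreen = prescreen)
  if (!is.null(labels)) d$label <- labels
  utils::write.csv(d, path, row.names = FALSE)
  invisible(d)
}

#' Write or read a feature matrix as CSV
#'
#' Header row of canonical feature names, one row per segment.
#'
#' @param x Feature matrix (rows = segments).
#' @param path CSV path.
#' @return `read_feature_matrix` returns the matrix.
#' @export
write_feature_matrix <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  as.matrix(utils::read.csv(path, check.names = FALSE))
}
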
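# Minimal European Data Format (EDF) support: fixed-layout ASCII header
# plus 16-bit little-endian sample records. Covers plain continuous EDF
# (no EDF+ annotations), which is what single-channel quality checking
# needs.

edf_pad <- function(x, width) formatC(as.character(x), width = width,
                                      flag = "-")

#' Write a single-channel EDF file
#'
#' @param x Numeric signal in microvolts.
#' @param path Output file path.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_name Signal label stored in the header.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(x, path, sampling_rate, channel_name = "EEG") {
  x <- as.numeric(x)
  fs <- as.integer(sampling_rate)
  n_rec <- ceiling(length(x) / fs)
  x <- c(x, numeric(n_rec * fs - length(x)))
  phys_min <- min(x) - 1e-3
  phys_max <- max(x) + 1e-3
  dig_min <- -32768L; dig_max <- 32767L
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  digital <- as.integer(round((x - phys_min) / gain) + dig_min)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("X X X", 80),
    "01.01.00", "00.00.00",
    edf_pad(256 + 256, 8), edf_pad("", 44), edf_pad(n_rec, 8),
    edf_pad(1, 8), edf_pad(1, 4))
  signal_header <- paste0(
    edf_pad(channel_name, 16), edf_pad("simulated", 80), edf_pad("uV", 8),
    edf_pad(sprintf("%.3f", phys_min), 8),
    edf_pad(sprintf("%.3f", phys_max), 8),
    edf_pad(dig_min, 8), edf_pad(dig_max, 8), edf_pad("", 80),
    edf_pad(fs, 8), edf_pad("", 32))
  writeChar(paste0(header, signal_header), con, eos = NULL)
  writeBin(digital, con, size = 2, endian = "little")
  invisible(path)
}

#' Read one channel from an EDF file
#'
#' Parses the fixed-layout EDF header, selects a channel by label (or
#' the first channel), applies the physical calibration and concatenates
#' the data records.
#'
#' @param path EDF file path.
#' @param channel Channel label to extract; `NULL` takes the first
#'   channel. Annotation channels are never selected by default.
#' @return List with `signal` (microvolts), `sampling_rate` (Hz) and
#'   `channel` (label).
#' @export
read_edf <- function(path, channel = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                                   # version
  rd(80); rd(80); rd(8); rd(8)            # ids + dates
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) trimws(vapply(seq_len(ns), function(i) rd(w), ""))
  labels <- fld(16)
  fld(80); units <- fld(8)
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)
  n_samp <- as.integer(fld(8))
  fld(32)
  seek(con, header_bytes)
  if (is.null(channel)) {
    ch <- which(!grepl("annotation", tolower(labels)))[1]
    if (is.na(ch)) stop("no data channel in EDF file")
  } else {
    ch <- match(channel, labels)
    if (is.na(ch)) stop("channel '", channel, "' not found; available: ",
                        paste(labels, collapse = ", "))
  }
  per_rec <- sum(n_samp)
  raw <- readBin(con, integer(), n = per_rec * n_rec, size = 2,
                 endian = "little")
  offsets <- c(0L, cumsum(n_samp))
  sel <- unlist(lapply(seq_len(n_rec) - 1L, function(r)
    r * per_rec + (offsets[ch] + 1L):offsets[ch + 1L]))
  gain <- (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
  sig <- (raw[sel] - dig_min[ch]) * gain + phys_min[ch]
  list(signal = sig, sampling_rate = n_samp[ch] / rec_dur,
       channel = labels[ch], unit = units[ch])
}
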
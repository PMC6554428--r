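## Minimal European Data Format (EDF) I/O.
##
## EDF stores a fixed-width ASCII header (256 bytes plus 256 per signal)
## followed by data records of 16-bit little-endian integers, one block of
## ns[i] samples per signal per record, scaled linearly between a physical
## and a digital range. This implementation covers continuous equal-rate
## signals, which is all the decoders need; annotations (EDF+) are not
## supported.

padField <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1L, width)
}

#' EDF file I/O
#'
#' Writes an [EEGRecording-class] to a 16-bit EDF file (one data record
#' per second) and reads it back. The physical range per channel is the
#' symmetric range covering the data, so quantization error is bounded by
#' `max(abs(x)) / 32767` per channel.
#'
#' @param rec an [EEGRecording-class]; the sampling rate must be a whole
#'   number of samples per second.
#' @param path file path.
#' @return `readEDF()`: an [EEGRecording-class].
#' @export
#' @examples
#' rec <- generateBackground(synthConfig(duration_s = 2, fs = 250, seed = 1))
#' f <- tempfile(fileext = ".edf")
#' writeEDF(rec, f)
#' rec2 <- readEDF(f)
#' max(abs(eegData(rec) - eegData(rec2)))  # quantization only
writeEDF <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- rec@fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  fs <- as.integer(round(fs))
  nchan <- nrow(rec@data)
  nsamp <- ncol(rec@data)
  ndr <- as.integer(ceiling(nsamp / fs))
  ## pad the tail of the last record with zeros
  x <- matrix(0, nchan, ndr * fs)
  x[, seq_len(nsamp)] <- rec@data
  physMax <- pmax(apply(abs(x), 1L, max), 1e-6)
  dig <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    padField("0", 8),                                  # version
    padField("X X X X", 80),                           # patient id
    padField("Startdate X X X X", 80),                 # recording id
    padField("01.01.00", 8), padField("00.00.00", 8),  # date, time
    padField(256L * (1L + nchan), 8),                  # header bytes
    padField("", 44),                                  # reserved
    padField(ndr, 8),                                  # n data records
    padField(1, 8),                                    # record duration (s)
    padField(nchan, 4))                                # n signals
  writeChar(hdr, con, eos = NULL)
  sigHdr <- paste0(
    paste(padField(rec@labels, 16), collapse = ""),
    paste(rep(padField("", 80), nchan), collapse = ""),       # transducer
    paste(rep(padField("uV", 8), nchan), collapse = ""),      # dimension
    paste(padField(sprintf("%.6g", -physMax), 8), collapse = ""),
    paste(padField(sprintf("%.6g", physMax), 8), collapse = ""),
    paste(rep(padField(-dig, 8), nchan), collapse = ""),
    paste(rep(padField(dig, 8), nchan), collapse = ""),
    paste(rep(padField("", 80), nchan), collapse = ""),       # prefilter
    paste(rep(padField(fs, 8), nchan), collapse = ""),        # samples/rec
    paste(rep(padField("", 32), nchan), collapse = ""))       # reserved
  writeChar(sigHdr, con, eos = NULL)

  scale <- dig / physMax
  for (r in seq_len(ndr)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(nchan)) {
      v <- as.integer(round(pmin(pmax(x[ch, cols] * scale[ch], -dig), dig)))
      writeBin(v, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname writeEDF
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rdChar <- function(n) readChar(con, n, useBytes = TRUE)
  rdNum <- function(n) as.numeric(trimws(rdChar(n)))
  rdChar(8 + 80 + 80 + 8 + 8)
  hdrBytes <- rdNum(8)
  rdChar(44)
  ndr <- as.integer(rdNum(8))
  recDur <- rdNum(8)
  nchan <- as.integer(rdNum(4))
  labels <- trimws(vapply(seq_len(nchan), function(i) rdChar(16), ""))
  rdChar(80 * nchan)               # transducer
  rdChar(8 * nchan)                # dimension
  physMin <- vapply(seq_len(nchan), function(i) rdNum(8), 0)
  physMax <- vapply(seq_len(nchan), function(i) rdNum(8), 0)
  digMin <- vapply(seq_len(nchan), function(i) rdNum(8), 0)
  digMax <- vapply(seq_len(nchan), function(i) rdNum(8), 0)
  rdChar(80 * nchan)               # prefilter
  ns <- vapply(seq_len(nchan), function(i) as.integer(rdNum(8)), 0L)
  rdChar(32 * nchan)               # reserved
  stopifnot(hdrBytes == 256 * (1 + nchan))

  x <- matrix(0, nchan, ndr * ns[1L])
  if (length(unique(ns)) != 1L)
    stop("mixed per-signal sampling rates are not supported")
  for (r in seq_len(ndr)) {
    for (ch in seq_len(nchan)) {
      v <- readBin(con, "integer", n = ns[ch], size = 2L, signed = TRUE,
                   endian = "little")
      g <- (physMax[ch] - physMin[ch]) / (digMax[ch] - digMin[ch])
      x[ch, ((r - 1L) * ns[ch] + 1L):(r * ns[ch])] <-
        physMin[ch] + g * (v - digMin[ch])
    }
  }
  EEGRecording(x, labels, fs = ns[1L] / recDur)
}
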
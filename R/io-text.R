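#' Delimited-text EEG I/O
#'
#' Plain-text exchange format for recordings: a header row of column
#' names, a first column `time_s`, and one column per channel in
#' microvolts. The reader infers the sampling rate from the time column
#' unless `fs` is given. Channel-label matching elsewhere in the package
#' is case-insensitive, so case need not round-trip.
#'
#' @param rec an [EEGRecording-class].
#' @param path file path.
#' @param sep field separator.
#' @return `readEEGText()`: an [EEGRecording-class].
#' @export
#' @examples
#' rec <- generateBackground(synthConfig(duration_s = 1, fs = 250, seed = 1))
#' f <- tempfile(fileext = ".tsv")
#' writeEEGText(rec, f)
#' rec2 <- readEEGText(f)
#' all.equal(eegData(rec), eegData(rec2))
writeEEGText <- function(rec, path, sep = "\t") {
  stopifnot(is(rec, "EEGRecording"))
  n <- ncol(rec@data)
  df <- data.frame(time_s = (seq_len(n) - 1L) / rec@fs,
                   t(rec@data), check.names = FALSE)
  names(df) <- c("time_s", rec@labels)
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeEEGText
#' @param fs sampling rate in Hz; if `NULL`, inferred from the time column.
#' @export
readEEGText <- function(path, sep = "\t", fs = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  if (ncol(df) < 2L) stop("need a time column plus at least one channel")
  if (is.null(fs)) {
    dt <- diff(df[[1L]])
    if (length(dt) == 0L || any(dt <= 0))
      stop("cannot infer sampling rate from the time column")
    fs <- 1 / stats::median(dt)
    fs <- round(fs, 6)
  }
  EEGRecording(t(as.matrix(df[, -1L, drop = FALSE])),
               labels = names(df)[-1L], fs = fs)
}

#' Intent-track I/O
#'
#' Ground-truth intent tracks (from [generateSession()]) are stored as
#' CSV with columns `onset_s`, `duration_s`, `intent`.
#'
#' @param track data frame with columns `onset_s`, `duration_s`, `intent`.
#' @param path file path.
#' @export
writeIntentTrack <- function(track, path) {
  stopifnot(all(c("onset_s", "duration_s", "intent") %in% names(track)))
  utils::write.csv(track[, c("onset_s", "duration_s", "intent")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeIntentTrack
#' @export
readIntentTrack <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
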
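## Double-blink detection by the counting-trough rule: in a 0.3-30 Hz
## filtered Fp2 block, count local minima deeper than -h that are at
## least beta * d apart; two or more troughs in a 1.5 s block is the
## conscious double-blink gesture.

localMinima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2L:(n - 1L)
  ## strict on the left, non-strict on the right: a plateau trough is
  ## attributed to its first sample
  i[x[i] < x[i - 1L] & x[i] <= x[i + 1L]]
}

#' Calibrate the trough-height threshold h
#'
#' Estimates the minimum absolute trough height from calibration blinks:
#' the mean over blink trials of the per-trial deepest trough, scaled by
#' a safety factor `alpha` so blinks at least as strong as the trained
#' strength are reliably caught.
#'
#' @param trials a [TrialSet-class] of calibration trials (raw Fp2 data;
#'   trials labeled `blink` are used, or all trials if no such label
#'   exists), or a list of numeric vectors of already-filtered Fp2 series.
#' @param alpha safety factor in `(0, 1]`.
#' @param band blink band-pass in Hz (applied to `TrialSet` input only).
#' @return The threshold `h` in uV.
#' @export
#' @examples
#' x1 <- -100 * sin(pi * seq(0, 1, length.out = 50))  # one 100 uV trough
#' x2 <- -120 * sin(pi * seq(0, 1, length.out = 50))
#' calibrateH(list(x1, x2), alpha = 0.5)  # 55
calibrateH <- function(trials, alpha = 0.5, band = c(0.3, 30)) {
  if (is(trials, "TrialSet")) {
    keep <- if ("blink" %in% trials@labels)
      trials@labels == "blink" else rep(TRUE, length(trials@labels))
    fp2 <- matchChannels(trials@channels, "Fp2")
    series <- lapply(trials@trials[keep], function(x)
      bandpass1d(x[fp2, ], band[1], band[2], trials@fs))
  } else {
    series <- lapply(trials, as.numeric)
  }
  if (length(series) == 0L) stop("no blink trials supplied", call. = FALSE)
  depths <- vapply(series, function(x) {
    m <- localMinima(x)
    m <- m[x[m] < 0]
    if (length(m) == 0L) NA_real_ else max(-x[m])
  }, 0)
  if (all(is.na(depths)))
    stop("calibration failure: no troughs found in any trial",
         call. = FALSE)
  alpha * mean(depths, na.rm = TRUE)
}

#' Count blink troughs in a filtered Fp2 block
#'
#' Scans a 0.3-30 Hz filtered Fp2 series for local minima at or below
#' `-h`, accepting them greedily left-to-right subject to a minimum
#' spacing of `beta * d_s` seconds between accepted troughs.
#'
#' @param x numeric vector, a filtered Fp2 block.
#' @param params a [BlinkParams-class].
#' @param fs sampling rate in Hz.
#' @return Integer trough count (0 for degenerate input).
#' @export
countTroughs <- function(x, params, fs) {
  stopifnot(is(params, "BlinkParams"))
  minSep <- ceiling(params@beta * params@d_s * fs)
  cand <- localMinima(x)
  cand <- cand[x[cand] <= -params@h]
  count <- 0L
  lastAccepted <- -Inf
  for (i in cand) {
    if (i - lastAccepted >= minSep) {
      count <- count + 1L
      lastAccepted <- i
    }
  }
  count
}

#' Detect a conscious double blink in a window
#'
#' Band-passes the Fp2 channel of a decoding window to 0.3-30 Hz and
#' returns `TRUE` when the trough count reaches
#' `params@countThreshold`. A positive detection makes the controller
#' hover and toggle flight modes.
#'
#' @param window an [EpochWindow-class] (or [EEGRecording-class])
#'   containing `Fp2`.
#' @param params a [BlinkParams-class].
#' @param band blink band-pass in Hz.
#' @return Logical.
#' @export
detectBlink <- function(window, params, band = c(0.3, 30)) {
  stopifnot(is(window, "EEGRecording"))
  fp2 <- getChannel(window, "Fp2")
  x <- bandpass1d(fp2, band[1], band[2], window@fs)
  countTroughs(x, params, window@fs) >= params@countThreshold
}
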
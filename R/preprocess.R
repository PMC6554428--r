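## Zero-phase Butterworth band-pass on a single series, with odd-reflection
## padding so filter transients do not leak into short decoding windows.
bandpass1d <- function(x, lo, hi, fs, order = 4) {
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  n <- length(x)
  pad <- min(n - 1L, as.integer(ceiling(3 * fs / lo)))
  if (pad > 0) {
    left <- 2 * x[1] - x[(pad + 1L):2L]
    right <- 2 * x[n] - x[(n - 1L):(n - pad)]
    y <- signal::filtfilt(bf, c(left, x, right))
    y[(pad + 1L):(pad + n)]
  } else {
    signal::filtfilt(bf, x)
  }
}

#' Zero-phase band-pass filter
#'
#' Filters every channel with a 4th-order Butterworth band-pass applied
#' forward and backward (zero phase), so trough positions and window
#' timing are not shifted. The three bands used by the decoders are
#' 0.3-30 Hz (blink), 5-40 Hz (SSVEP) and 9-12 Hz (motor imagery).
#'
#' @param rec an [EEGRecording-class] (or [EpochWindow-class]).
#' @param lo,hi band edges in Hz; `0 < lo < hi < fs/2`.
#' @param order filter order (4).
#' @return An object of the same class with every channel filtered.
#' @export
#' @examples
#' cfg <- synthConfig(duration_s = 2, fs = 250, seed = 1)
#' filtered <- bandpassFilter(generateBackground(cfg), 9, 12)
bandpassFilter <- function(rec, lo, hi, order = 4) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- rec@fs
  if (!is.finite(lo) || !is.finite(hi) || lo <= 0 || hi <= lo || hi >= fs / 2)
    stop("invalid band: need 0 < lo < hi < fs/2", call. = FALSE)
  out <- rec
  out@data <- t(apply(rec@data, 1L, bandpass1d, lo = lo, hi = hi, fs = fs,
                      order = order))
  rownames(out@data) <- rec@labels
  out
}

#' Common average reference
#'
#' Subtracts the instantaneous mean of a channel subset from each channel
#' in that subset; channels outside the subset (here Oz and Fp2) are left
#' untouched. The motor-imagery pipeline re-references the 10
#' sensorimotor channels this way after band-pass filtering.
#'
#' @param rec an [EEGRecording-class].
#' @param subset channel names to re-reference (default the 10
#'   sensorimotor channels); matched case-insensitively; at least 2.
#' @return An object of the same class, re-referenced.
#' @export
carFilter <- function(rec, subset = miChannels()) {
  stopifnot(is(rec, "EEGRecording"))
  idx <- matchChannels(rec@labels, subset)
  if (length(idx) < 2L)
    stop("CAR needs at least 2 channels", call. = FALSE)
  out <- rec
  avg <- colMeans(rec@data[idx, , drop = FALSE])
  out@data[idx, ] <- sweep(rec@data[idx, , drop = FALSE], 2L, avg)
  out
}

#' Sliding decoding windows
#'
#' Cuts a recording into the online decoding stream: `length_s` windows
#' starting every `stride_s` seconds (1.5 s windows at a 1 s command
#' cadence, so consecutive windows overlap by 0.5 s). Windows are emitted
#' while a full window fits; a recording shorter than one window yields
#' an empty list.
#'
#' @param rec an [EEGRecording-class].
#' @param length_s window length in seconds.
#' @param stride_s stride between window onsets in seconds.
#' @return List of [EpochWindow-class] objects.
#' @export
#' @examples
#' cfg <- synthConfig(duration_s = 4.5, fs = 250, seed = 1)
#' length(windowStream(generateBackground(cfg)))  # onsets 0, 1, 2, 3
windowStream <- function(rec, length_s = 1.5, stride_s = 1.0) {
  stopifnot(is(rec, "EEGRecording"))
  dur <- duration(rec)
  if (dur < length_s) return(list())
  onsets <- seq(0, dur - length_s + 1e-9, by = stride_s)
  lapply(onsets, function(o) EpochWindow(rec, o, length_s))
}

#' Motor-imagery preprocessing
#'
#' The fixed preprocessing in front of the CICSP decoder: 9-12 Hz
#' band-pass (mu band) followed by a common average reference over the 10
#' sensorimotor channels.
#'
#' @param rec an [EEGRecording-class] or [EpochWindow-class].
#' @param band mu band edges in Hz.
#' @param channels CAR subset.
#' @return Same class as `rec`, preprocessed.
#' @export
preprocessMI <- function(rec, band = c(9, 12), channels = miChannels()) {
  carFilter(bandpassFilter(rec, band[1], band[2]), channels)
}

#' @rdname preprocessMI
#' @param trials a [TrialSet-class] of raw trials.
#' @return `preprocessMITrials()`: a `TrialSet` of preprocessed trials.
#' @export
preprocessMITrials <- function(trials, band = c(9, 12),
                               channels = miChannels()) {
  stopifnot(is(trials, "TrialSet"))
  out <- trials
  out@trials <- lapply(trials@trials, function(x) {
    rec <- EEGRecording(x, trials@channels, trials@fs)
    eegData(preprocessMI(rec, band, channels))
  })
  out
}
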
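#' EEGRecording: multichannel EEG time series
#'
#' Container for a channels-by-samples matrix of scalp EEG in microvolts,
#' together with channel labels and the sampling rate.
#'
#' @slot data numeric matrix, channels x samples (uV).
#' @slot labels character vector of unique channel names, one per row.
#' @slot fs sampling rate in Hz.
#' @export
setClass("EEGRecording",
  representation(data = "matrix", labels = "character", fs = "numeric"))

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@data))
    msg <- c(msg, "'data' must be a numeric matrix")
  if (nrow(object@data) != length(object@labels))
    msg <- c(msg, "rows of 'data' must match length of 'labels'")
  if (anyDuplicated(tolower(object@labels)))
    msg <- c(msg, "channel labels must be unique")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param data numeric matrix, channels x samples (uV).
#' @param labels character vector of channel names (defaults to rownames).
#' @param fs sampling rate in Hz.
#' @return An [EEGRecording-class] object.
#' @export
#' @examples
#' rec <- EEGRecording(matrix(rnorm(24), 2), c("Oz", "Fp2"), fs = 100)
#' samplingRate(rec)
EEGRecording <- function(data, labels = rownames(data), fs) {
  data <- as.matrix(data)
  if (is.null(labels)) stop("channel labels are required")
  rownames(data) <- labels
  new("EEGRecording", data = data, labels = as.character(labels), fs = fs)
}

#' EpochWindow: one decoding segment
#'
#' A fixed-length segment cut from an [EEGRecording-class], carrying its
#' onset time in the parent recording. Decoding windows are 1.5 s long.
#'
#' @slot onset_s onset of the window in seconds from recording start.
#' @export
setClass("EpochWindow", contains = "EEGRecording",
  representation(onset_s = "numeric"))

#' @rdname EpochWindow-class
#' @param rec an [EEGRecording-class].
#' @param onset_s onset in seconds.
#' @param length_s window length in seconds.
#' @return An `EpochWindow`.
#' @export
EpochWindow <- function(rec, onset_s, length_s = 1.5) {
  n <- round(length_s * rec@fs)
  i0 <- round(onset_s * rec@fs) + 1L
  if (i0 < 1L || i0 + n - 1L > ncol(rec@data))
    stop("window [", onset_s, ", ", onset_s + length_s,
         "] s falls outside the recording")
  new("EpochWindow", data = rec@data[, i0:(i0 + n - 1L), drop = FALSE],
      labels = rec@labels, fs = rec@fs, onset_s = onset_s)
}

#' TrialSet: labeled calibration trials
#'
#' A list of equally-shaped channels-by-samples trial matrices with one
#' class label per trial, as produced in a calibration session. Label
#' domains in this package are `left`/`right` (motor imagery),
#' `f12.4`/`f18` (SSVEP) and `blink`/`noblink`.
#'
#' @slot trials list of numeric matrices, all channels x samples.
#' @slot labels character vector, one label per trial.
#' @slot channels character vector of channel names (matrix rows).
#' @slot fs sampling rate in Hz.
#' @export
setClass("TrialSet",
  representation(trials = "list", labels = "character",
                 channels = "character", fs = "numeric"))

setValidity("TrialSet", function(object) {
  msg <- character()
  if (length(object@trials) != length(object@labels))
    msg <- c(msg, "one label per trial is required")
  if (length(object@trials) == 0L)
    msg <- c(msg, "at least one trial is required")
  dims <- vapply(object@trials, function(x) dim(as.matrix(x)), integer(2))
  if (length(object@trials) && any(dims[1, ] != length(object@channels)))
    msg <- c(msg, "every trial must have one row per channel")
  if (length(object@trials) && length(unique(dims[2, ])) > 1L)
    msg <- c(msg, "all trials must have the same number of samples")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @rdname TrialSet-class
#' @param trials list of channels x samples matrices.
#' @param labels one class label per trial.
#' @param channels channel names.
#' @param fs sampling rate in Hz.
#' @export
TrialSet <- function(trials, labels, channels, fs) {
  new("TrialSet", trials = lapply(trials, as.matrix),
      labels = as.character(labels), channels = as.character(channels),
      fs = fs)
}

#' SynthConfig: parameters of the synthetic-EEG generator
#'
#' All amplitudes are in microvolts. The generator draws pink
#' (1/f power) background noise on every channel, adds a mu-band
#' oscillation on the sensorimotor channels, and the `inject*` operations
#' add SSVEP, lateralized mu attenuation (ERD) and blink troughs on top.
#'
#' @slot duration_s recording length in seconds.
#' @slot fs sampling rate in Hz (1000 by default; 250 is a fast-test mode).
#' @slot channels ordered channel labels.
#' @slot noiseScale RMS amplitude of the pink background noise (uV).
#' @slot muAmp amplitude of the sensorimotor mu oscillation (uV).
#' @slot muFreq mu oscillation frequency in Hz.
#' @slot ssvepAmp SSVEP fundamental amplitude at Oz (uV).
#' @slot ssvepHarmonicRatio amplitude of the first harmonic relative to the
#'   fundamental.
#' @slot erdDepth fractional mu-power attenuation in `[0, 1]` on the
#'   hemisphere contralateral to the imagined hand.
#' @slot erdGain ipsilateral mu gain factor: the ipsilateral mu component is
#'   scaled by `1 + erdDepth * erdGain` (event-related synchronization).
#' @slot blinkDepth blink trough magnitude at Fp2 (uV).
#' @slot blinkWidth blink pulse width in seconds.
#' @slot seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @export
setClass("SynthConfig",
  representation(duration_s = "numeric", fs = "numeric",
                 channels = "character", noiseScale = "numeric",
                 muAmp = "numeric", muFreq = "numeric",
                 ssvepAmp = "numeric", ssvepHarmonicRatio = "numeric",
                 erdDepth = "numeric", erdGain = "numeric",
                 blinkDepth = "numeric", blinkWidth = "numeric",
                 seed = "numeric"))

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (object@duration_s <= 0) msg <- c(msg, "'duration_s' must be > 0")
  if (object@fs <= 0) msg <- c(msg, "'fs' must be > 0")
  if (object@erdDepth < 0 || object@erdDepth > 1)
    msg <- c(msg, "'erdDepth' must lie in [0, 1]")
  if (object@noiseScale < 0) msg <- c(msg, "'noiseScale' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname SynthConfig-class
#' @param duration_s,fs,channels,noiseScale,muAmp,muFreq,ssvepAmp,ssvepHarmonicRatio,erdDepth,erdGain,blinkDepth,blinkWidth,seed see slots.
#' @return A `SynthConfig`.
#' @export
#' @examples
#' cfg <- synthConfig(duration_s = 1.5, seed = 7)
#' rec <- generateBackground(cfg)
#' dim(eegData(rec))
synthConfig <- function(duration_s, fs = 1000, channels = bciChannels(),
                        noiseScale = 5, muAmp = 10, muFreq = 10,
                        ssvepAmp = 5, ssvepHarmonicRatio = 0.5,
                        erdDepth = 0.8, erdGain = 0.25,
                        blinkDepth = 150, blinkWidth = 0.2, seed = 1L) {
  new("SynthConfig", duration_s = duration_s, fs = fs,
      channels = channels, noiseScale = noiseScale, muAmp = muAmp,
      muFreq = muFreq, ssvepAmp = ssvepAmp,
      ssvepHarmonicRatio = ssvepHarmonicRatio, erdDepth = erdDepth,
      erdGain = erdGain, blinkDepth = blinkDepth, blinkWidth = blinkWidth,
      seed = seed)
}

#' BlinkParams: trough-counting detector parameters
#'
#' @slot d_s nominal spacing between the two troughs of a conscious
#'   double blink, in seconds (0.75 s).
#' @slot h minimum absolute trough height in uV; estimated from
#'   calibration data by [calibrateH()].
#' @slot countThreshold number of accepted troughs that constitutes a
#'   detection (2: one per blink of the double-blink gesture).
#' @slot beta spacing tolerance: accepted troughs must be at least
#'   `beta * d_s` apart.
#' @export
setClass("BlinkParams",
  representation(d_s = "numeric", h = "numeric",
                 countThreshold = "numeric", beta = "numeric"))

setValidity("BlinkParams", function(object) {
  msg <- character()
  if (object@d_s <= 0) msg <- c(msg, "'d_s' must be > 0")
  if (object@h <= 0) msg <- c(msg, "'h' must be > 0")
  if (object@countThreshold < 1) msg <- c(msg, "'countThreshold' must be >= 1")
  if (object@beta <= 0 || object@beta > 1)
    msg <- c(msg, "'beta' must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname BlinkParams-class
#' @param d_s,h,countThreshold,beta see slots.
#' @export
blinkParams <- function(h, d_s = 0.75, countThreshold = 2, beta = 0.6) {
  new("BlinkParams", d_s = d_s, h = h, countThreshold = countThreshold,
      beta = beta)
}

#' SpatialFilterBank: CSP filters from simultaneous diagonalization
#'
#' Rows of `W` are spatial filters sorted by decreasing eigenvalue; the
#' eigenvalue of a filter is the share of class-1 variance it passes, so
#' `W %*% (C1 + C2) %*% t(W)` is the identity.
#'
#' @slot W filters x channels matrix.
#' @slot eigvals eigenvalues in `[0, 1]`, decreasing.
#' @export
setClass("SpatialFilterBank",
  representation(W = "matrix", eigvals = "numeric"))

setValidity("SpatialFilterBank", function(object) {
  msg <- character()
  if (nrow(object@W) != length(object@eigvals))
    msg <- c(msg, "one eigenvalue per filter row is required")
  if (any(object@eigvals < -1e-8 | object@eigvals > 1 + 1e-8))
    msg <- c(msg, "eigenvalues must lie in [0, 1]")
  if (is.unsorted(rev(object@eigvals), strictly = FALSE))
    msg <- c(msg, "eigenvalues must be sorted decreasing")
  if (length(msg)) msg else TRUE
})

#' CICSPModel: trained complete-information CSP decoder
#'
#' Holds the CSP filter bank split into the `2m` edge filters (`Q1`) and
#' the intermediate filters (`Q2`), the PCA loading that compresses the
#' intermediate log-variance features to `k` dimensions, and a linear SVM
#' over the concatenated feature vector `F = [f1, f2']`.
#'
#' @slot filters a [SpatialFilterBank-class].
#' @slot m edge filters kept per side.
#' @slot k dimensions retained from the intermediate features (0 = plain CSP).
#' @slot channels channel names the filters apply to, in order.
#' @slot classes the two class labels, sorted; `classes[1]` is the class
#'   whose variance the first filter maximizes.
#' @slot pcaCenter,pcaLoading centering vector and unit-norm loading matrix
#'   of the PCA on intermediate features (empty when `k = 0`).
#' @slot svm fitted `e1071::svm` object (linear kernel).
#' @slot trainAccuracy training-set accuracy, fraction in `[0, 1]`.
#' @export
setClass("CICSPModel",
  representation(filters = "SpatialFilterBank", m = "numeric", k = "numeric",
                 channels = "character", classes = "character",
                 pcaCenter = "numeric", pcaLoading = "matrix",
                 svm = "ANY", trainAccuracy = "numeric"))

#' CCAResult: SSVEP classification outcome
#'
#' @slot coefficients named numeric vector of first canonical correlations,
#'   one per candidate frequency (names are the frequencies in Hz).
#' @slot decision the winning frequency in Hz (largest coefficient, ties
#'   broken toward the lower frequency).
#' @export
setClass("CCAResult",
  representation(coefficients = "numeric", decision = "numeric"))

setValidity("CCAResult", function(object) {
  msg <- character()
  if (is.null(names(object@coefficients)))
    msg <- c(msg, "'coefficients' must be named by frequency")
  if (any(object@coefficients < -1e-8 | object@coefficients > 1 + 1e-8))
    msg <- c(msg, "canonical correlations must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
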
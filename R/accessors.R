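#' Accessors for EEG containers
#'
#' @param x an [EEGRecording-class], [EpochWindow-class] or
#'   [TrialSet-class].
#' @param channel a channel name (matched case-insensitively).
#' @name eeg-accessors
NULL

#' @rdname eeg-accessors
#' @return `eegData()`: the channels x samples matrix.
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))
#' @rdname eeg-accessors
setMethod("eegData", "EEGRecording", function(x) x@data)

#' @rdname eeg-accessors
#' @return `channelNames()`: character vector of channel labels.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname eeg-accessors
setMethod("channelNames", "EEGRecording", function(x) x@labels)
#' @rdname eeg-accessors
setMethod("channelNames", "TrialSet", function(x) x@channels)

#' @rdname eeg-accessors
#' @return `samplingRate()`: sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname eeg-accessors
setMethod("samplingRate", "EEGRecording", function(x) x@fs)
#' @rdname eeg-accessors
setMethod("samplingRate", "TrialSet", function(x) x@fs)

#' @rdname eeg-accessors
#' @return `nSamples()`: number of time samples.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname eeg-accessors
setMethod("nSamples", "EEGRecording", function(x) ncol(x@data))

#' @rdname eeg-accessors
#' @return `duration()`: recording length in seconds.
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))
#' @rdname eeg-accessors
setMethod("duration", "EEGRecording", function(x) ncol(x@data) / x@fs)

#' @rdname eeg-accessors
#' @return `getChannel()`: numeric vector, the samples of one channel.
#' @export
setGeneric("getChannel", function(x, channel) standardGeneric("getChannel"))
#' @rdname eeg-accessors
setMethod("getChannel", "EEGRecording", function(x, channel) {
  x@data[matchChannels(x@labels, channel), ]
})

#' @rdname eeg-accessors
#' @return `onset()`: window onset in seconds.
#' @export
setGeneric("onset", function(x) standardGeneric("onset"))
#' @rdname eeg-accessors
setMethod("onset", "EpochWindow", function(x) x@onset_s)

#' @rdname eeg-accessors
#' @return `nTrials()`: number of trials.
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @rdname eeg-accessors
setMethod("nTrials", "TrialSet", function(x) length(x@trials))

#' @rdname eeg-accessors
#' @return `trialLabels()`: character vector of per-trial labels.
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))
#' @rdname eeg-accessors
setMethod("trialLabels", "TrialSet", function(x) x@labels)

#' @rdname eeg-accessors
#' @return `trialData()`: list of trial matrices.
#' @export
setGeneric("trialData", function(x) standardGeneric("trialData"))
#' @rdname eeg-accessors
setMethod("trialData", "TrialSet", function(x) x@trials)

#' Filter bank and model accessors
#'
#' @param x a [SpatialFilterBank-class] or [CICSPModel-class].
#' @name csp-accessors
NULL

#' @rdname csp-accessors
#' @return `spatialFilters()`: the filters x channels matrix `W`.
#' @export
setGeneric("spatialFilters", function(x) standardGeneric("spatialFilters"))
#' @rdname csp-accessors
setMethod("spatialFilters", "SpatialFilterBank", function(x) x@W)
#' @rdname csp-accessors
setMethod("spatialFilters", "CICSPModel", function(x) x@filters@W)

#' @rdname csp-accessors
#' @return `cspEigenvalues()`: decreasing eigenvalues in `[0, 1]`.
#' @export
setGeneric("cspEigenvalues", function(x) standardGeneric("cspEigenvalues"))
#' @rdname csp-accessors
setMethod("cspEigenvalues", "SpatialFilterBank", function(x) x@eigvals)
#' @rdname csp-accessors
setMethod("cspEigenvalues", "CICSPModel", function(x) x@filters@eigvals)

#' @rdname csp-accessors
#' @return `trainAccuracy()`: training accuracy as a fraction.
#' @export
setGeneric("trainAccuracy", function(x) standardGeneric("trainAccuracy"))
#' @rdname csp-accessors
setMethod("trainAccuracy", "CICSPModel", function(x) x@trainAccuracy)

#' CCA result accessors
#'
#' @param x a [CCAResult-class].
#' @name cca-accessors
NULL

#' @rdname cca-accessors
#' @return `ccaCoefficients()`: named vector of canonical correlations.
#' @export
setGeneric("ccaCoefficients", function(x) standardGeneric("ccaCoefficients"))
#' @rdname cca-accessors
setMethod("ccaCoefficients", "CCAResult", function(x) x@coefficients)

#' @rdname cca-accessors
#' @return `decision()`: the selected frequency in Hz.
#' @export
setGeneric("decision", function(x) standardGeneric("decision"))
#' @rdname cca-accessors
setMethod("decision", "CCAResult", function(x) x@decision)

setMethod("show", "EEGRecording", function(object) {
  cat("EEGRecording: ", nrow(object@data), " channels x ",
      ncol(object@data), " samples (", format(duration(object)),
      " s @ ", object@fs, " Hz)\n", sep = "")
  cat("  channels: ", paste(object@labels, collapse = " "), "\n", sep = "")
})

setMethod("show", "EpochWindow", function(object) {
  cat("EpochWindow: onset ", object@onset_s, " s, ",
      ncol(object@data) / object@fs, " s @ ", object@fs, " Hz, ",
      nrow(object@data), " channels\n", sep = "")
})

setMethod("show", "TrialSet", function(object) {
  tab <- table(object@labels)
  cat("TrialSet: ", length(object@trials), " trials (",
      paste(names(tab), tab, sep = "=", collapse = ", "), "), ",
      length(object@channels), " channels @ ", object@fs, " Hz\n", sep = "")
})

setMethod("show", "SpatialFilterBank", function(object) {
  cat("SpatialFilterBank: ", nrow(object@W), " filters over ",
      ncol(object@W), " channels\n", sep = "")
  cat("  eigenvalues: ", paste(sprintf("%.3f", object@eigvals),
      collapse = " "), "\n", sep = "")
})

setMethod("show", "CICSPModel", function(object) {
  cat("CICSPModel: m = ", object@m, ", k = ", object@k, " (",
      2 * object@m + object@k, " features), classes ",
      paste(object@classes, collapse = "/"), "\n", sep = "")
  cat("  channels: ", paste(object@channels, collapse = " "), "\n", sep = "")
  cat("  training accuracy: ",
      sprintf("%.1f%%", 100 * object@trainAccuracy), "\n", sep = "")
})

setMethod("show", "CCAResult", function(object) {
  cat("CCAResult: decision ", object@decision, " Hz\n", sep = "")
  cat("  rho:", paste(names(object@coefficients),
      sprintf("%.3f", object@coefficients), sep = "=", collapse = ", "),
      "\n")
})
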
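## Synthetic EEG with the statistical structure each decoder assumes:
## pink-noise background, sensorimotor mu rhythm, lateralized mu
## attenuation (ERD) for motor imagery, Oz sinusoids plus first harmonic
## for SSVEP, and large negative Fp2 troughs for blinks.

## Pink noise (power spectral density ~ 1/f) by spectral shaping of white
## noise; normalized to the requested RMS. Consumes RNG.
pinkNoise <- function(n, rms) {
  if (rms == 0) return(numeric(n))
  w <- stats::rnorm(n)
  sp <- stats::fft(w)
  ## one-sided frequency index; DC removed, amplitude ~ f^(-1/2)
  k <- c(1, seq_len(n - 1))
  k <- pmin(k, n - k + 1)
  shape <- 1 / sqrt(k)
  shape[1] <- 0
  x <- Re(stats::fft(sp * shape, inverse = TRUE)) / n
  x * (rms / stats::sd(x))
}

#' Generate background EEG
#'
#' Draws pink-noise background on every channel and adds a mu-band
#' oscillation (default 10 Hz) on the 10 sensorimotor channels. Each
#' sensorimotor channel gets its own oscillator phase, drawn once per
#' channel: scalp mu is not phase-locked across hemispheres, and a
#' phase-incoherent rhythm survives the common-average reference that the
#' motor-imagery pipeline applies downstream. Output is bit-identical for
#' identical config (including seed).
#'
#' @param config a [SynthConfig-class].
#' @return An [EEGRecording-class], channels x `round(duration_s * fs)`.
#' @export
#' @examples
#' rec <- generateBackground(synthConfig(duration_s = 1.5, seed = 1))
#' dim(eegData(rec))  # 12 x 1500
generateBackground <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  n <- round(config@duration_s * config@fs)
  if (n < 1) stop("duration too short for one sample", call. = FALSE)
  chans <- config@channels
  withSeed(config@seed, {
    mu_idx <- which(tolower(chans) %in% tolower(miChannels()))
    phases <- stats::runif(length(chans), 0, 2 * pi)
    tt <- (seq_len(n) - 1) / config@fs
    x <- matrix(0, length(chans), n)
    for (i in seq_along(chans)) {
      x[i, ] <- pinkNoise(n, config@noiseScale)
      if (i %in% mu_idx && config@muAmp > 0) {
        x[i, ] <- x[i, ] +
          config@muAmp * sin(2 * pi * config@muFreq * tt + phases[i])
      }
    }
    EEGRecording(x, chans, config@fs)
  })
}

#' Inject an SSVEP response
#'
#' Adds `amp * sin(2 pi f t) + amp * harmonicRatio * sin(2 pi 2f t)` to
#' the Oz channel only — the occipital response to a stimulus flickering
#' at `freq`, with its first harmonic. All other channels are untouched.
#'
#' @param rec an [EEGRecording-class] containing an `Oz` channel.
#' @param freq stimulus frequency in Hz; must satisfy `freq < fs/4` so the
#'   harmonic stays below Nyquist.
#' @param amp fundamental amplitude in uV.
#' @param harmonicRatio harmonic amplitude relative to the fundamental.
#' @return The modified recording.
#' @export
injectSSVEP <- function(rec, freq, amp, harmonicRatio = 0.5) {
  stopifnot(is(rec, "EEGRecording"))
  if (freq <= 0 || freq >= rec@fs / 4)
    stop("need 0 < freq < fs/4 so the first harmonic is below Nyquist",
         call. = FALSE)
  i <- matchChannels(rec@labels, "Oz")
  tt <- (seq_len(ncol(rec@data)) - 1) / rec@fs
  rec@data[i, ] <- rec@data[i, ] +
    amp * sin(2 * pi * freq * tt) +
    amp * harmonicRatio * sin(2 * pi * 2 * freq * tt)
  rec
}

#' Inject lateralized mu attenuation (ERD/ERS)
#'
#' Emulates motor imagery of one hand: the mu-band (9-12 Hz) component of
#' the sensorimotor channels contralateral to the imagined hand is scaled
#' by `1 - depth` (event-related desynchronization) and the ipsilateral
#' channels by `1 + depth * gain` (synchronization in the non-task
#' hemisphere). Left-hand imagery attenuates the right-hemisphere set
#' (FC2, FC4, C2, C4, CP2) and vice versa.
#'
#' @param rec an [EEGRecording-class].
#' @param side `"left"` or `"right"` imagined hand.
#' @param depth fractional mu-power attenuation in `[0, 1]`.
#' @param gain ipsilateral gain factor.
#' @param band mu band in Hz.
#' @return The modified recording.
#' @export
injectMIERD <- function(rec, side = c("left", "right"), depth,
                        gain = 0.25, band = c(9, 12)) {
  stopifnot(is(rec, "EEGRecording"))
  side <- match.arg(side)
  if (!is.finite(depth) || depth < 0 || depth > 1)
    stop("'depth' must lie in [0, 1]", call. = FALSE)
  if (depth == 0) return(rec)
  contra <- hemisphereChannels(if (side == "left") "right" else "left")
  ipsi <- hemisphereChannels(side)
  scaleBand <- function(idx, factor) {
    for (i in idx) {
      mu <- bandpass1d(rec@data[i, ], band[1], band[2], rec@fs)
      rec@data[i, ] <<- rec@data[i, ] + (factor - 1) * mu
    }
  }
  scaleBand(matchChannels(rec@labels, contra), 1 - depth)
  scaleBand(matchChannels(rec@labels, ipsi), 1 + depth * gain)
  rec
}

#' Inject blink troughs
#'
#' Subtracts a raised-cosine (Hann) pulse of magnitude `depth` and width
#' `width_s` from the Fp2 channel at each requested time — the
#' large-magnitude negative deflection a downward eye movement produces
#' at the right prefrontal electrode. Other channels are untouched.
#'
#' @param rec an [EEGRecording-class] containing `Fp2`.
#' @param times pulse centers in seconds; pulses must not overlap.
#' @param depth trough magnitude in uV (positive; the pulse is negative).
#' @param width_s pulse width in seconds.
#' @return The modified recording.
#' @export
injectBlinks <- function(rec, times, depth, width_s = 0.2) {
  stopifnot(is(rec, "EEGRecording"))
  if (length(times) == 0L) return(rec)
  times <- sort(as.numeric(times))
  dur <- duration(rec)
  if (any(times < 0) || any(times > dur))
    stop("blink times must lie within the recording", call. = FALSE)
  if (length(times) > 1L && any(diff(times) < width_s))
    stop("blink pulses overlap: spacing must exceed width_s", call. = FALSE)
  i <- matchChannels(rec@labels, "Fp2")
  tt <- (seq_len(ncol(rec@data)) - 1) / rec@fs
  for (tc in times) {
    u <- (tt - tc) / width_s          # support [-1/2, 1/2]
    inside <- abs(u) <= 0.5
    rec@data[i, inside] <- rec@data[i, inside] -
      depth * 0.5 * (1 + cos(2 * pi * u[inside]))
  }
  rec
}

#' Generate labeled calibration trials
#'
#' Convenience generators for calibration populations: raw (unfiltered)
#' trial sets for each decoder, one independent background draw per trial
#' (seeds `seed + 1, seed + 2, ...`).
#'
#' `generateMITrials()` yields `left`/`right` trials with ERD injected at
#' `config@erdDepth`; `generateSSVEPTrials()` yields `f12.4`/`f18` trials
#' with the SSVEP sinusoids at Oz; `generateBlinkTrials()` yields
#' `blink`/`noblink` trials, the blink trials carrying two troughs 0.75 s
#' apart (the double-blink gesture).
#'
#' @param nPerClass trials per class.
#' @param config a [SynthConfig-class]; `duration_s` is forced to
#'   `length_s`.
#' @param length_s trial length in seconds.
#' @param freqs the two SSVEP stimulus frequencies in Hz.
#' @return A [TrialSet-class] of raw trials.
#' @export
#' @examples
#' cfg <- synthConfig(duration_s = 1.5, fs = 250, seed = 3)
#' generateMITrials(5, cfg)
generateMITrials <- function(nPerClass, config, length_s = 1.5) {
  makeTrials(nPerClass, config, length_s, c("left", "right"),
    function(rec, label) {
      injectMIERD(rec, side = label, depth = config@erdDepth,
                  gain = config@erdGain)
    })
}

#' @rdname generateMITrials
#' @export
generateSSVEPTrials <- function(nPerClass, config, length_s = 1.5,
                                freqs = c(12.4, 18)) {
  labels <- paste0("f", freqs)
  makeTrials(nPerClass, config, length_s, labels,
    function(rec, label) {
      f <- freqs[match(label, labels)]
      injectSSVEP(rec, f, config@ssvepAmp, config@ssvepHarmonicRatio)
    })
}

#' @rdname generateMITrials
#' @export
generateBlinkTrials <- function(nPerClass, config, length_s = 1.5) {
  half <- 0.375                      # troughs at mid -/+ d/2, d = 0.75 s
  mid <- length_s / 2
  makeTrials(nPerClass, config, length_s, c("blink", "noblink"),
    function(rec, label) {
      if (label == "blink") {
        injectBlinks(rec, c(mid - half, mid + half),
                     depth = config@blinkDepth,
                     width_s = config@blinkWidth)
      } else rec
    })
}

makeTrials <- function(nPerClass, config, length_s, classes, injector) {
  stopifnot(nPerClass >= 1L)
  labels <- rep(classes, each = nPerClass)
  trials <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    cfg <- config
    cfg@duration_s <- length_s
    cfg@seed <- config@seed + i
    trials[[i]] <- eegData(injector(generateBackground(cfg), labels[i]))
  }
  TrialSet(trials, labels, config@channels, config@fs)
}

#' Generate a scripted session
#'
#' Concatenates intent spans into one continuous recording with a
#' ground-truth intent track, for end-to-end controller tests. Each span
#' is an independent background draw (seed `seed + span index`) with the
#' intent's signature injected: `left`/`right` spans carry ERD,
#' `f12.4`/`f18` spans carry the SSVEP sinusoids, `blink` spans carry two
#' troughs 0.75 s apart centered in the span, and `idle` spans are
#' background only.
#'
#' @param script data frame with columns `intent` (one of `left`,
#'   `right`, `f12.4`, `f18`, `blink`, `idle`) and `duration_s`, or a
#'   list of `c(intent, duration)` pairs.
#' @param config a [SynthConfig-class]; its `duration_s` is ignored.
#' @return A list with elements `recording` ([EEGRecording-class]),
#'   `truth` (data frame `onset_s`, `duration_s`, `intent`) and
#'   `sampleIntent` (character vector, one intent per sample).
#' @export
#' @examples
#' cfg <- synthConfig(duration_s = 1, fs = 250, seed = 5)
#' s <- generateSession(data.frame(intent = c("left", "idle"),
#'                                 duration_s = c(3, 2)), cfg)
#' s$truth
generateSession <- function(script, config) {
  if (is.list(script) && !is.data.frame(script)) {
    script <- data.frame(
      intent = vapply(script, function(p) as.character(p[[1]]), ""),
      duration_s = vapply(script, function(p) as.numeric(p[[2]]), 0))
  }
  if (nrow(script) == 0L) stop("empty session script", call. = FALSE)
  valid <- c("left", "right", "f12.4", "f18", "blink", "idle")
  if (!all(script$intent %in% valid))
    stop("unknown intent(s): ",
         paste(setdiff(script$intent, valid), collapse = ", "),
         call. = FALSE)
  pieces <- vector("list", nrow(script))
  sampleIntent <- character(0)
  for (i in seq_len(nrow(script))) {
    cfg <- config
    cfg@duration_s <- script$duration_s[i]
    cfg@seed <- config@seed + i
    rec <- generateBackground(cfg)
    rec <- switch(script$intent[i],
      left = injectMIERD(rec, "left", config@erdDepth, config@erdGain),
      right = injectMIERD(rec, "right", config@erdDepth, config@erdGain),
      f12.4 = injectSSVEP(rec, 12.4, config@ssvepAmp,
                          config@ssvepHarmonicRatio),
      f18 = injectSSVEP(rec, 18, config@ssvepAmp,
                        config@ssvepHarmonicRatio),
      blink = {
        mid <- script$duration_s[i] / 2
        injectBlinks(rec, c(mid - 0.375, mid + 0.375),
                     depth = config@blinkDepth,
                     width_s = config@blinkWidth)
      },
      idle = rec)
    pieces[[i]] <- eegData(rec)
    sampleIntent <- c(sampleIntent,
                      rep(script$intent[i], ncol(pieces[[i]])))
  }
  recording <- EEGRecording(do.call(cbind, pieces), config@channels,
                            config@fs)
  truth <- data.frame(
    onset_s = cumsum(c(0, script$duration_s[-nrow(script)])),
    duration_s = script$duration_s,
    intent = script$intent)
  list(recording = recording, truth = truth, sampleIntent = sampleIntent)
}
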
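## Mode-switching flight controller: every 1.5 s window is first checked
## for a double blink (hover + mode toggle); otherwise the window is
## decoded by whichever mode is active - motor imagery steers
## left-forward/right-forward, SSVEP steers rise/fall.

commandKinds <- c("LEFT_FORWARD", "RIGHT_FORWARD", "RISE", "FALL",
                  "HOVER_SWITCH")

#' Command payloads
#'
#' Fixed velocity/yaw payload per command kind: left/right-forward fly at
#' 0.25 m/s with a -42/+42 degree yaw, rise climbs at 0.2 m/s, fall
#' descends at 0.3 m/s, and hover (the blink response) zeroes everything
#' while the flight mode toggles.
#'
#' @param kind one of `LEFT_FORWARD`, `RIGHT_FORWARD`, `RISE`, `FALL`,
#'   `HOVER_SWITCH`.
#' @return A list with `kind`, `yaw_deg`, `forward_mps`, `vertical_mps`.
#' @export
#' @examples
#' commandPayload("LEFT_FORWARD")
commandPayload <- function(kind) {
  kind <- match.arg(kind, commandKinds)
  payload <- switch(kind,
    LEFT_FORWARD = c(-42, 0.25, 0),
    RIGHT_FORWARD = c(42, 0.25, 0),
    RISE = c(0, 0, 0.2),
    FALL = c(0, 0, -0.3),
    HOVER_SWITCH = c(0, 0, 0))
  list(kind = kind, yaw_deg = payload[1], forward_mps = payload[2],
       vertical_mps = payload[3])
}

#' Bundle the per-mode decoders
#'
#' Collects everything [controllerStep()] needs: the trained CICSP model,
#' calibrated blink parameters and the SSVEP configuration, including the
#' frequency-to-command map (12.4 Hz = top LED = rise, 18 Hz = bottom
#' LED = fall).
#'
#' @param cicsp a [CICSPModel-class].
#' @param blink a [BlinkParams-class].
#' @param ssvepFreqs candidate SSVEP frequencies in Hz.
#' @param ssvepMap named character vector mapping frequency to command.
#' @param nh harmonics for the SSVEP references.
#' @param ssvepBand,miBand analysis bands in Hz.
#' @return A list of class `decoderBundle`.
#' @export
decoderBundle <- function(cicsp, blink, ssvepFreqs = c(12.4, 18),
                          ssvepMap = c("12.4" = "RISE", "18" = "FALL"),
                          nh = 2, ssvepBand = c(5, 40), miBand = c(9, 12)) {
  stopifnot(is(cicsp, "CICSPModel"), is(blink, "BlinkParams"))
  structure(list(cicsp = cicsp, blink = blink, ssvepFreqs = ssvepFreqs,
                 ssvepMap = ssvepMap, nh = nh, ssvepBand = ssvepBand,
                 miBand = miBand),
            class = "decoderBundle")
}

#' One controller step
#'
#' Decodes a single raw 1.5 s window. The blink check runs first; a
#' detection emits `HOVER_SWITCH` and toggles the flight mode. Otherwise
#' the window goes to the active mode: MI mode preprocesses (mu band +
#' CAR) and runs the online CICSP prediction; SSVEP mode runs the CCA
#' classifier.
#'
#' @param window a raw [EpochWindow-class] (all 12 montage channels).
#' @param mode current flight mode, `"MI"` or `"SSVEP"`.
#' @param models a [decoderBundle()].
#' @param refractory if `TRUE`, skip the blink check for this window
#'   (the stride immediately after a mode switch, so one physical blink
#'   spanning two overlapping windows cannot toggle twice).
#' @return A list with `command` (a [commandPayload()]), `mode` (mode
#'   after the step) and `diagnostics`.
#' @export
controllerStep <- function(window, mode = c("SSVEP", "MI"), models,
                           refractory = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(models, "decoderBundle"))
  if (!refractory && detectBlink(window, models$blink)) {
    newMode <- if (mode == "MI") "SSVEP" else "MI"
    return(list(command = commandPayload("HOVER_SWITCH"), mode = newMode,
                diagnostics = list(blink = TRUE)))
  }
  if (mode == "MI") {
    win <- preprocessMI(window, band = models$miBand,
                        channels = models$cicsp@channels)
    side <- predictMIOnline(win, models$cicsp)
    kind <- if (side == "left") "LEFT_FORWARD" else "RIGHT_FORWARD"
    list(command = commandPayload(kind), mode = mode,
         diagnostics = list(blink = FALSE, mi = side))
  } else {
    res <- classifySSVEP(window, freqs = models$ssvepFreqs,
                         nh = models$nh, band = models$ssvepBand)
    kind <- unname(models$ssvepMap[as.character(decision(res))])
    list(command = commandPayload(kind), mode = mode,
         diagnostics = list(blink = FALSE, rho = ccaCoefficients(res)))
  }
}

#' Run a full decoding session
#'
#' Streams a recording through [windowStream()] (1.5 s windows, 1 s
#' stride) and [controllerStep()], producing exactly one command per
#' stride. Deterministic: re-running on the same recording yields an
#' identical log.
#'
#' @param rec a raw [EEGRecording-class], at least 1.5 s long.
#' @param models a [decoderBundle()].
#' @param initialMode flight mode at takeoff (`"SSVEP"` by default).
#' @param length_s,stride_s window length and command cadence in seconds.
#' @return The command log: a data frame with one row per stride and
#'   columns `onset_s`, `mode_before`, `command`, `yaw_deg`,
#'   `forward_mps`, `vertical_mps`.
#' @export
runSession <- function(rec, models, initialMode = c("SSVEP", "MI"),
                       length_s = 1.5, stride_s = 1.0) {
  initialMode <- match.arg(initialMode)
  windows <- windowStream(rec, length_s, stride_s)
  if (length(windows) == 0L) {
    return(data.frame(onset_s = numeric(0), mode_before = character(0),
                      command = character(0), yaw_deg = numeric(0),
                      forward_mps = numeric(0), vertical_mps = numeric(0)))
  }
  mode <- initialMode
  refractory <- FALSE
  rows <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    st <- controllerStep(windows[[i]], mode, models,
                         refractory = refractory)
    cmd <- st$command
    rows[[i]] <- data.frame(onset_s = onset(windows[[i]]),
                            mode_before = mode, command = cmd$kind,
                            yaw_deg = cmd$yaw_deg,
                            forward_mps = cmd$forward_mps,
                            vertical_mps = cmd$vertical_mps)
    refractory <- cmd$kind == "HOVER_SWITCH"
    mode <- st$mode
  }
  do.call(rbind, rows)
}
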
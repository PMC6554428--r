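## Flight-performance metrics: Fitts-law index of difficulty and the
## analogous information transfer rate, average gate acquisition time,
## out-of-boundary rate and percent task correct, computed from per-
## subject flight-trial counts.

#' Fitts-law index of difficulty
#'
#' `log2(distance / width + 1)` in bits: the difficulty of steering
#' through a gate of the given width from the given starting distance.
#' The bundled tasks use a 4.75 m displacement to the gate center and a
#' 3.5 m gate.
#'
#' @param distance_m start-to-gate-center displacement in meters.
#' @param width_m gate width in meters.
#' @return Difficulty in bits.
#' @export
#' @examples
#' indexOfDifficulty(4.75, 3.5)  # 1.237 bits
indexOfDifficulty <- function(distance_m = 4.75, width_m = 3.5) {
  stopifnot_scalar(distance_m, "distance_m")
  stopifnot_scalar(width_m, "width_m")
  log2(distance_m / width_m + 1)
}

#' Average gate acquisition time
#'
#' Total flight time divided by the number of gate passages, in minutes
#' per gate.
#'
#' @param totalTime_min total flight time in minutes.
#' @param gates number of passes through the gate.
#' @return Minutes per gate.
#' @export
agat <- function(totalTime_min, gates) {
  stopifnot_scalar(totalTime_min, "totalTime_min")
  if (!is.numeric(gates) || gates <= 0)
    stop("undefined metric: no gate passages", call. = FALSE)
  totalTime_min / gates
}

#' Out-of-boundaries rate
#'
#' Boundary crossings per unit time. The `"table"` variant (default)
#' divides crossings by the total flight time in minutes. The
#' `"equation"` variant divides by total time over average trial time,
#' which algebraically reduces to crossings per trial; both readings are
#' provided because they disagree (see the methods vignette).
#'
#' @param crossings number of flights beyond the safety boundaries.
#' @param totalTime_min total flight time in minutes.
#' @param trials number of trials (required for the `"equation"` variant).
#' @param variant `"table"` or `"equation"`.
#' @return Crossings per minute (`"table"`) or per trial (`"equation"`).
#' @export
obut <- function(crossings, totalTime_min, trials = NULL,
                 variant = c("table", "equation")) {
  variant <- match.arg(variant)
  if (!is.numeric(totalTime_min) || totalTime_min <= 0)
    stop("undefined metric: zero flight time", call. = FALSE)
  if (variant == "table") {
    crossings / totalTime_min
  } else {
    if (is.null(trials)) stop("'trials' is required for the equation variant")
    crossings / (totalTime_min / (totalTime_min / trials))
  }
}

#' Percent task correct
#'
#' Gate passages over gate passages plus failures, as a fraction. For
#' the two-gate task each trial offers two passages, so
#' `failures = 2 * trials - gates`.
#'
#' @param gates number of passes through the gate.
#' @param failures number of failed passages.
#' @return Fraction in `[0, 1]`.
#' @export
ptc <- function(gates, failures) {
  if (gates + failures <= 0)
    stop("undefined metric: no attempts", call. = FALSE)
  gates / (gates + failures)
}

#' Analogous information transfer rate
#'
#' The Fitts-law index of difficulty divided by the (unrounded) average
#' gate acquisition time, in bits per minute — an ITR analogue for a
#' physical steering task.
#'
#' @inheritParams agat
#' @inheritParams indexOfDifficulty
#' @return Bits per minute.
#' @export
#' @examples
#' analogousITR(20.7, 39)  # 2.33 bit/min
analogousITR <- function(totalTime_min, gates, distance_m = 4.75,
                         width_m = 3.5) {
  indexOfDifficulty(distance_m, width_m) / agat(totalTime_min, gates)
}

#' Summarize flight logs
#'
#' Computes the per-subject metrics and their arithmetic mean (the
#' `Average` row) from raw trial counts. All intermediates stay
#' unrounded; rounding happens only in printing.
#'
#' @param logs data frame with columns `subject`, `trials`,
#'   `gates_passed`, `boundary_crossings`, `total_flight_time_min`.
#' @param gates_per_trial passages offered per trial (1 for the
#'   single-gate task, 2 for the two-gate task); must be the same for all
#'   rows.
#' @param distance_m,width_m task geometry in meters.
#' @param obut_variant see [obut()].
#' @return Data frame with one row per subject plus an `Average` row and
#'   columns `subject`, `trials`, `gates_passed`, `boundary_crossings`,
#'   `total_flight_time_min`, `agat_min_per_gate`, `obut_per_min`,
#'   `ptc_pct`, `itr_bit_per_min`.
#' @export
#' @examples
#' summarizeFlights(flightLog("complex"))
summarizeFlights <- function(logs, gates_per_trial = 2,
                             distance_m = 4.75, width_m = 3.5,
                             obut_variant = "table") {
  need <- c("subject", "trials", "gates_passed", "boundary_crossings",
            "total_flight_time_min")
  if (!all(need %in% names(logs)))
    stop("flight log must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(logs) < 1L) stop("at least one log row is required")
  if (length(gates_per_trial) != 1L)
    stop("mixed gates_per_trial is not supported", call. = FALSE)
  with(logs, stopifnot(all(gates_passed <= trials * gates_per_trial)))
  out <- data.frame(
    subject = as.character(logs$subject),
    trials = logs$trials,
    gates_passed = logs$gates_passed,
    boundary_crossings = logs$boundary_crossings,
    total_flight_time_min = logs$total_flight_time_min)
  out$agat_min_per_gate <- mapply(agat, logs$total_flight_time_min,
                                  logs$gates_passed)
  out$obut_per_min <- mapply(function(cr, tt, n)
    obut(cr, tt, n, obut_variant),
    logs$boundary_crossings, logs$total_flight_time_min, logs$trials)
  failures <- gates_per_trial * logs$trials - logs$gates_passed
  out$ptc_pct <- 100 * mapply(ptc, logs$gates_passed, failures)
  out$itr_bit_per_min <- mapply(analogousITR, logs$total_flight_time_min,
                                logs$gates_passed,
                                MoreArgs = list(distance_m = distance_m,
                                                width_m = width_m))
  avg <- data.frame(subject = "Average",
                    t(colMeans(out[, -1L, drop = FALSE])))
  names(avg) <- names(out)
  rbind(out, avg)
}

#' Column mean of a success-rate table
#'
#' Arithmetic mean of a column of percentages, as printed in calibration
#' summaries (two decimals).
#'
#' @param column numeric vector of percentages.
#' @param digits decimals to round to; `NULL` returns the exact mean.
#' @return The mean percentage.
#' @export
tableMean <- function(column, digits = 2) {
  if (length(column) == 0L) stop("empty column", call. = FALSE)
  m <- mean(column)
  if (is.null(digits)) m else round(m, digits)
}
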
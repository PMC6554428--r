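#' Bundled study records
#'
#' Per-subject records from the published nine-subject quadcopter-BCI
#' study the package models, shipped as plain CSV under
#' `inst/extdata/`:
#'
#' * `flightLog("complex")` — the two-gate (S-route) task for subjects
#'   5-9: 20 trials each, successes (both gates), half successes (one
#'   gate), total gate passages, boundary crossings and total flight
#'   time in minutes.
#' * `flightLog("simple")` — the single-gate zig-zag task: 10 trials
#'   each, gate passages, boundary crossings and flight time.
#' * `calibrationRates()` — calibration-phase success rates (percent)
#'   for SSVEP, motor imagery (plain CSP and CICSP) and eye blinking,
#'   plus the entire-task rate, for all nine subjects.
#'
#' @param task `"complex"` or `"simple"`.
#' @return A data frame.
#' @export
#' @examples
#' summarizeFlights(flightLog("complex"))
#' tableMean(calibrationRates()$ssvep_pct)
flightLog <- function(task = c("complex", "simple")) {
  task <- match.arg(task)
  path <- system.file("extdata",
                      paste0(task, "_task_flight.csv"),
                      package = "hybridBCI", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname flightLog
#' @export
calibrationRates <- function() {
  path <- system.file("extdata", "calibration_success_rates.csv",
                      package = "hybridBCI", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
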
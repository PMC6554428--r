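#' @import methods
#' @importFrom stats cor fft prcomp predict rnorm runif sd
#' @importFrom signal butter filtfilt
#' @importFrom e1071 svm
NULL

## Montage used throughout: 12 scalp electrodes referenced to Cz.

#' Standard channel montage
#'
#' Channel labels of the 12-electrode montage the decoders expect:
#' ten sensorimotor electrodes for motor imagery, `Oz` for SSVEP and
#' `Fp2` for eye blinks.
#'
#' @return `bciChannels()`: character vector of the 12 montage labels.
#' @export
#' @examples
#' bciChannels()
#' miChannels()
bciChannels <- function() {
  c("CP1", "CP2", "FC1", "FC2", "FC3", "FC4",
    "C1", "C2", "C3", "C4", "Oz", "Fp2")
}

#' @rdname bciChannels
#' @return `miChannels()`: the 10 sensorimotor labels used for motor imagery.
#' @export
miChannels <- function() {
  c("CP1", "CP2", "FC1", "FC2", "FC3", "FC4", "C1", "C2", "C3", "C4")
}

#' @rdname bciChannels
#' @param side `"left"` or `"right"` scalp hemisphere.
#' @return `hemisphereChannels()`: the 5 sensorimotor labels on that side
#'   (odd indices = left hemisphere in the 10/20 convention).
#' @export
hemisphereChannels <- function(side = c("left", "right")) {
  side <- match.arg(side)
  if (side == "left") c("CP1", "FC1", "FC3", "C1", "C3")
  else c("CP2", "FC2", "FC4", "C2", "C4")
}

## Case-insensitive channel lookup; errors with a missing-channel message.
matchChannels <- function(labels, wanted, what = "channel") {
  idx <- match(tolower(wanted), tolower(labels))
  if (anyNA(idx)) {
    stop("missing ", what, "(s): ",
         paste(wanted[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG stream.
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (positive && x <= 0)) {
    stop("'", name, "' must be a single finite",
         if (positive) " positive", " number", call. = FALSE)
  }
  invisible(x)
}
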
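## SSVEP frequency recognition: canonical correlation between the Oz
## series and harmonic sin/cos reference sets at each candidate stimulus
## frequency; the frequency with the largest first canonical correlation
## wins.

#' Build a harmonic reference set
#'
#' Rows are `sin(2 pi k f t)`, `cos(2 pi k f t)` for `k = 1..nh`,
#' sampled at `t = 0, 1/fs, ...` — the Fourier series of the stimulus
#' period against which the Oz signal is correlated.
#'
#' @param freq stimulus frequency in Hz.
#' @param nh number of harmonics (2: fundamental plus first harmonic).
#' @param fs sampling rate in Hz; `nh * freq` must be below `fs/2`.
#' @param n number of samples.
#' @return A `(2 * nh) x n` matrix with rownames like `"sin1"`, `"cos1"`.
#' @export
#' @examples
#' dim(buildReference(12.4, 2, 1000, 1500))  # 4 x 1500
buildReference <- function(freq, nh = 2, fs, n) {
  if (freq <= 0 || nh < 1 || nh * freq >= fs / 2)
    stop("aliasing: need nh * freq < fs / 2", call. = FALSE)
  tt <- (seq_len(n) - 1) / fs
  Y <- matrix(0, 2 * nh, n)
  rn <- character(2 * nh)
  for (k in seq_len(nh)) {
    Y[2 * k - 1, ] <- sin(2 * pi * k * freq * tt)
    Y[2 * k, ] <- cos(2 * pi * k * freq * tt)
    rn[2 * k - 1] <- paste0("sin", k)
    rn[2 * k] <- paste0("cos", k)
  }
  rownames(Y) <- rn
  Y
}

#' First canonical correlation
#'
#' The maximal correlation between linear combinations `a' X` and `b' Y`
#' of two multichannel series, computed from the singular values of the
#' whitened cross-covariance. A ridge of `ridge * trace` is added to each
#' auto-covariance so near-singular reference sets (e.g. long coherent
#' sinusoids) stay numerically stable.
#'
#' @param X numeric vector or `p x n` matrix (rows are variables).
#' @param Y numeric vector or `q x n` matrix; same `n > max(p, q)`.
#' @param ridge relative ridge added to the auto-covariances.
#' @return The first canonical correlation in `[0, 1]`. Zero-variance `X`
#'   returns 0 with a warning.
#' @export
#' @examples
#' Y <- buildReference(12.4, 2, 1000, 1500)
#' ccaCoefficient(Y[1, ], Y)  # ~1: X lies in the span of Y
ccaCoefficient <- function(X, Y, ridge = 1e-8) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  Y <- if (is.matrix(Y)) Y else matrix(Y, nrow = 1)
  n <- ncol(X)
  if (ncol(Y) != n) stop("X and Y must have the same number of samples")
  if (n <= max(nrow(X), nrow(Y)))
    stop("need more samples than variables", call. = FALSE)
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  Cxx <- tcrossprod(Xc) / (n - 1)
  Cyy <- tcrossprod(Yc) / (n - 1)
  Cxy <- tcrossprod(Xc, Yc) / (n - 1)
  trX <- sum(diag(Cxx))
  if (trX <= 0) {
    warning("zero-variance X: canonical correlation set to 0")
    return(0)
  }
  Cxx <- Cxx + diag(ridge * trX, nrow(Cxx))
  Cyy <- Cyy + diag(ridge * sum(diag(Cyy)), nrow(Cyy))
  invSqrt <- function(M) {
    e <- eigen(M, symmetric = TRUE)
    vals <- pmax(e$values, .Machine$double.eps)
    e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors)
  }
  K <- invSqrt(Cxx) %*% Cxy %*% invSqrt(Cyy)
  rho <- svd(K, nu = 0, nv = 0)$d[1]
  min(max(rho, 0), 1)
}

#' Classify an SSVEP window
#'
#' Band-passes the window (5-40 Hz, covering the stimulus fundamentals
#' and their first harmonics), extracts the Oz channel and computes one
#' canonical correlation per candidate frequency against its harmonic
#' reference set. The decision is the frequency with the largest
#' coefficient; exact ties fall to the lower frequency.
#'
#' @param window an [EpochWindow-class] (or [EEGRecording-class])
#'   containing `Oz`.
#' @param freqs candidate stimulus frequencies in Hz (12.4 Hz = rise LED,
#'   18 Hz = fall LED).
#' @param nh harmonics per reference set.
#' @param band analysis band in Hz; `NULL` skips filtering (input already
#'   filtered).
#' @return A [CCAResult-class].
#' @export
classifySSVEP <- function(window, freqs = c(12.4, 18), nh = 2,
                          band = c(5, 40)) {
  stopifnot(is(window, "EEGRecording"), length(freqs) >= 1)
  x <- getChannel(window, "Oz")
  if (!is.null(band)) x <- bandpass1d(x, band[1], band[2], window@fs)
  freqs <- sort(freqs)               # ties fall to the lower frequency
  rho <- vapply(freqs, function(f) {
    Y <- buildReference(f, nh, window@fs, length(x))
    ccaCoefficient(x, Y)
  }, 0)
  names(rho) <- freqs
  new("CCAResult", coefficients = rho, decision = freqs[which.max(rho)])
}
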
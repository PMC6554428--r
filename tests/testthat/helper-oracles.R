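# Independent oracles used to validate the closed-form routines.

# Brute-force first canonical correlation: numerically maximize
# |cor(a'X, b'Y)| over the projection vectors with multistart
# quasi-Newton search. Independent of the SVD-based implementation.
bruteForceCCA <- function(X, Y, restarts = 8) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  Y <- if (is.matrix(Y)) Y else matrix(Y, nrow = 1)
  p <- nrow(X); q <- nrow(Y)
  obj <- function(par) {
    x <- drop(par[seq_len(p)] %*% X)
    y <- drop(par[p + seq_len(q)] %*% Y)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    -abs(stats::cor(x, y))
  }
  best <- 0
  for (r in seq_len(restarts)) {
    o <- stats::optim(stats::rnorm(p + q), obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
    best <- max(best, -o$value)
  }
  best
}

# Monte-Carlo check that no random unit vector beats the top CSP filter's
# Rayleigh quotient w'C1w / w'(C1+C2)w.
maxRandomRayleigh <- function(C1, C2, draws = 1e4) {
  C <- nrow(C1)
  Cc <- C1 + C2
  best <- -Inf
  for (i in seq_len(draws %/% 100)) {
    Wm <- matrix(stats::rnorm(100 * C), 100, C)
    num <- rowSums((Wm %*% C1) * Wm)
    den <- rowSums((Wm %*% Cc) * Wm)
    best <- max(best, max(num / den))
  }
  best
}

# Random symmetric positive definite matrix.
randomSPD <- function(n) {
  A <- matrix(stats::rnorm(n * n), n)
  crossprod(A) / n + diag(0.1, n)
}
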
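## Complete-information CSP: standard CSP edge filters (first m and last
## m rows of W) provide the discriminative log-variance features f1; the
## normally discarded intermediate filters are kept, their log-variance
## features compressed by PCA to k dimensions (f2'), and the
## concatenation F = [f1, f2'] is classified with a linear SVM.

#' Class-average normalized covariances
#'
#' Per trial, the spatial covariance `X X' / trace(X X')` (so every trial
#' contributes equal total power), averaged within each class. Trials are
#' expected to be mu-band filtered and common-average referenced.
#'
#' @param trials a [TrialSet-class] with exactly two label values.
#' @return Named list of two symmetric unit-trace matrices, in sorted
#'   label order.
#' @export
classCovariances <- function(trials) {
  stopifnot(is(trials, "TrialSet"))
  classes <- sort(unique(trials@labels))
  if (length(classes) != 2L)
    stop("exactly two classes are required, got: ",
         paste(classes, collapse = ", "), call. = FALSE)
  covs <- lapply(classes, function(cl) {
    xs <- trials@trials[trials@labels == cl]
    acc <- 0
    for (x in xs) {
      C <- tcrossprod(x)
      acc <- acc + C / sum(diag(C))
    }
    S <- acc / length(xs)
    (S + t(S)) / 2
  })
  names(covs) <- classes
  covs
}

#' Solve the CSP eigenproblem
#'
#' Simultaneous diagonalization of the two class covariances: `W` solves
#' `C1 w = lambda (C1 + C2) w`, rows sorted by decreasing eigenvalue, so
#' the first filters maximize class-1 variance relative to total variance
#' and the last filters maximize class-2 variance. A relative ridge keeps
#' the composite positive definite. Row signs are fixed so each filter's
#' largest-magnitude coefficient is positive.
#'
#' @param C1,C2 symmetric covariance matrices of the two classes.
#' @param ridge relative ridge on the composite covariance.
#' @return A [SpatialFilterBank-class] with
#'   `W %*% (C1 + C2) %*% t(W) = I` within tolerance.
#' @export
#' @examples
#' fb <- solveCSP(diag(c(2, 1)) / 3, diag(c(1, 2)) / 3)
#' cspEigenvalues(fb)  # 2/3, 1/3
solveCSP <- function(C1, C2, ridge = 1e-9) {
  stopifnot(is.matrix(C1), is.matrix(C2), all(dim(C1) == dim(C2)))
  ## the ridge is split across the two classes so that directions the
  ## data do not span (e.g. the common-average direction after CAR,
  ## which has zero variance in both classes) get eigenvalue 1/2 and
  ## sort into the middle of the bank instead of displacing an edge
  ## filter
  eps <- ridge * sum(diag(C1 + C2)) / 2
  C1r <- (C1 + t(C1)) / 2 + diag(eps, nrow(C1))
  C2r <- (C2 + t(C2)) / 2 + diag(eps, nrow(C2))
  Cc <- C1r + C2r
  e <- eigen(Cc, symmetric = TRUE)
  if (any(e$values <= 0))
    stop("numerical failure: composite covariance not positive definite",
         call. = FALSE)
  P <- diag(1 / sqrt(e$values), length(e$values)) %*% t(e$vectors)
  S <- P %*% C1r %*% t(P)
  b <- eigen((S + t(S)) / 2, symmetric = TRUE)   # values decreasing
  W <- t(b$vectors) %*% P
  ## sign convention: largest-|coefficient| positive per filter
  for (i in seq_len(nrow(W))) {
    j <- which.max(abs(W[i, ]))
    if (W[i, j] < 0) W[i, ] <- -W[i, ]
  }
  new("SpatialFilterBank", W = W,
      eigvals = pmin(pmax(b$values, 0), 1))
}

#' Normalized log-variance features
#'
#' For a projected series `Z` (filters x samples), the feature of filter
#' `i` is `log((Z Z')_ii / trace(Z Z'))` — the log share of total
#' variance that filter passes, so `sum(exp(lambda)) = 1` and the
#' features are invariant to amplitude scaling.
#'
#' @param Z numeric matrix, filters x samples.
#' @return Numeric vector, one feature per filter row. Zero-power rows
#'   are clamped at `log(1e-12)` with a warning.
#' @export
logvarFeatures <- function(Z) {
  Z <- if (is.matrix(Z)) Z else matrix(Z, nrow = 1)
  if (ncol(Z) < 2L) stop("need at least 2 samples", call. = FALSE)
  p <- rowSums(Z^2)
  tot <- sum(p)
  if (tot <= 0) stop("all-zero projection", call. = FALSE)
  if (any(p == 0))
    warning("zero-power filter row(s): clamped at log(1e-12)")
  log(pmax(p / tot, 1e-12))
}

edgeRows <- function(C, m) c(seq_len(m), (C - m + 1L):C)

## F = [f1, f2'] for one preprocessed trial matrix (full-window path).
cicspFeatures <- function(model, x) {
  W <- model@filters@W
  C <- nrow(W)
  f1 <- logvarFeatures(W[edgeRows(C, model@m), , drop = FALSE] %*% x)
  if (model@k == 0L) return(f1)
  mid <- W[-edgeRows(C, model@m), , drop = FALSE]
  lam2 <- logvarFeatures(mid %*% x)
  f2p <- as.numeric(crossprod(model@pcaLoading, lam2 - model@pcaCenter))
  c(f1, f2p)
}

#' Fit a complete-information CSP decoder
#'
#' Trains the full motor-imagery pipeline on preprocessed (mu-band
#' filtered, common-average referenced) calibration trials: CSP filter
#' bank, `2m` edge-filter log-variance features `f1`, PCA over the
#' intermediate-filter features jointly across both classes with the
#' top-`k` loading kept (`f2'`), and a linear SVM on `F = [f1, f2']`.
#' `k = 0` drops the intermediate path and yields plain CSP.
#'
#' @param trials a [TrialSet-class] of preprocessed trials, two classes.
#' @param m edge filters per side (2).
#' @param k intermediate dimensions kept (1; 0 = plain CSP).
#' @param cost SVM regularization parameter.
#' @param channels channels used for decoding, in filter order (the 10
#'   sensorimotor channels); extracted from each trial case-insensitively.
#' @return A [CICSPModel-class].
#' @export
#' @examples
#' cfg <- synthConfig(duration_s = 1.5, fs = 250, seed = 11)
#' tr <- preprocessMITrials(generateMITrials(8, cfg))
#' fitCICSP(tr)
fitCICSP <- function(trials, m = 2, k = 1, cost = 1,
                     channels = miChannels()) {
  stopifnot(is(trials, "TrialSet"))
  idx <- matchChannels(trials@channels, channels)
  C <- length(idx)
  if (2 * m >= C) stop("2 * m must be below the channel count")
  if (k > C - 2 * m)
    stop("no intermediate filters left: need k <= C - 2m", call. = FALSE)
  xs <- lapply(trials@trials, function(x) x[idx, , drop = FALSE])
  sub <- TrialSet(xs, trials@labels, channels, trials@fs)
  covs <- classCovariances(sub)
  fb <- solveCSP(covs[[1L]], covs[[2L]])
  W <- fb@W
  f1 <- t(vapply(xs, function(x)
    logvarFeatures(W[edgeRows(C, m), , drop = FALSE] %*% x), numeric(2 * m)))
  if (k > 0L) {
    lam2 <- t(vapply(xs, function(x)
      logvarFeatures(W[-edgeRows(C, m), , drop = FALSE] %*% x),
      numeric(C - 2 * m)))
    pc <- stats::prcomp(lam2, center = TRUE, scale. = FALSE)
    loading <- pc$rotation[, seq_len(k), drop = FALSE]
    center <- pc$center
    f2p <- sweep(lam2, 2L, center) %*% loading
    feats <- cbind(f1, f2p)
  } else {
    loading <- matrix(0, 0, 0)
    center <- numeric(0)
    feats <- f1
  }
  y <- factor(trials@labels, levels = sort(unique(trials@labels)))
  fit <- e1071::svm(feats, y, kernel = "linear", cost = cost,
                    scale = FALSE)
  acc <- mean(predict(fit, feats) == y)
  new("CICSPModel", filters = fb, m = m, k = k, channels = channels,
      classes = levels(y), pcaCenter = center, pcaLoading = loading,
      svm = fit, trainAccuracy = acc)
}

#' Batch prediction for preprocessed trials
#'
#' Full-window decoding: `f1` and `f2'` are both computed from the whole
#' trial. Use [predictMIOnline()] for the online sub-window variant.
#'
#' @param model a [CICSPModel-class].
#' @param newdata a [TrialSet-class], [EpochWindow-class] or single
#'   channels x samples matrix of preprocessed data.
#' @return Character vector of predicted class labels.
#' @export
predictCICSP <- function(model, newdata) {
  stopifnot(is(model, "CICSPModel"))
  xs <- if (is(newdata, "TrialSet")) {
    idx <- matchChannels(newdata@channels, model@channels)
    lapply(newdata@trials, function(x) x[idx, , drop = FALSE])
  } else if (is(newdata, "EEGRecording")) {
    idx <- matchChannels(newdata@labels, model@channels)
    list(newdata@data[idx, , drop = FALSE])
  } else {
    list(as.matrix(newdata))
  }
  feats <- t(vapply(xs, function(x) cicspFeatures(model, x),
                    numeric(2 * model@m + model@k)))
  as.character(predict(model@svm, feats))
}

#' Online motor-imagery prediction
#'
#' The online decoding of a 1.5 s window: `f1` comes from the full
#' window through the edge filters, while the window is split into three
#' 0.5 s sub-windows, each projected through the intermediate filters;
#' the three PCA-reduced intermediate feature vectors are averaged into
#' one `f2'`, and the classifier is applied to `[f1, f2']`.
#'
#' @param window an [EpochWindow-class] of preprocessed data, exactly
#'   `round(1.5 * fs)` samples.
#' @param model a [CICSPModel-class].
#' @param nSub number of sub-windows (3).
#' @return `"left"` or `"right"`.
#' @export
predictMIOnline <- function(window, model, nSub = 3L) {
  stopifnot(is(window, "EEGRecording"), is(model, "CICSPModel"))
  n <- ncol(window@data)
  if (n != round(1.5 * window@fs))
    stop("online decoding expects a 1.5 s window", call. = FALSE)
  idx <- matchChannels(window@labels, model@channels)
  x <- window@data[idx, , drop = FALSE]
  W <- model@filters@W
  C <- nrow(W)
  f1 <- logvarFeatures(W[edgeRows(C, model@m), , drop = FALSE] %*% x)
  if (model@k == 0L) {
    feats <- matrix(f1, nrow = 1)
  } else {
    mid <- W[-edgeRows(C, model@m), , drop = FALSE]
    len <- n %/% nSub
    f2sub <- vapply(seq_len(nSub), function(s) {
      xi <- x[, ((s - 1L) * len + 1L):(s * len), drop = FALSE]
      lam <- logvarFeatures(mid %*% xi)
      as.numeric(crossprod(model@pcaLoading, lam - model@pcaCenter))
    }, numeric(model@k))
    f2p <- if (model@k == 1L) mean(f2sub) else rowMeans(f2sub)
    feats <- matrix(c(f1, f2p), nrow = 1)
  }
  as.character(predict(model@svm, feats))
}

#' Decoder-model serialization
#'
#' Writes a decoder bundle (or a single [CICSPModel-class]) to one
#' self-describing file with a format version tag, and reads it back.
#'
#' @param model the object to store.
#' @param path file path.
#' @return `readDecoderModel()`: the stored object.
#' @export
writeDecoderModel <- function(model, path) {
  saveRDS(list(format = "hybridBCI-model", version = 1L,
               created = as.character(Sys.time()), model = model),
          path)
  invisible(path)
}

#' @rdname writeDecoderModel
#' @export
readDecoderModel <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "hybridBCI-model"))
    stop("not a decoder model file", call. = FALSE)
  obj$model
}
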
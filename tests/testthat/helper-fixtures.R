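# Shared fixtures. Most unit tests run at fs = 250 (the fast-test mode);
# simulation studies that mirror the calibration conditions use fs = 1000.

fastConfig <- function(duration_s = 1.5, seed = 1L, ...) {
  synthConfig(duration_s = duration_s, fs = 250, seed = seed, ...)
}

# A single Hann trough of given depth (uV) centered at `at` seconds.
hannTrough <- function(n, fs, at, depth, width_s = 0.2) {
  tt <- (seq_len(n) - 1) / fs
  u <- (tt - at) / width_s
  x <- numeric(n)
  inside <- abs(u) <= 0.5
  x[inside] <- -depth * 0.5 * (1 + cos(2 * pi * u[inside]))
  x
}

.fixtures <- new.env()

# CICSP model + blink params trained once at fs = 250 for controller tests.
fastModels <- function() {
  if (is.null(.fixtures$models)) {
    cfg <- fastConfig(seed = 301L)
    trials <- preprocessMITrials(generateMITrials(15, cfg))
    model <- fitCICSP(trials)
    bt <- generateBlinkTrials(5, fastConfig(seed = 401L))
    bp <- blinkParams(h = calibrateH(bt))
    .fixtures$models <- decoderBundle(model, bp)
  }
  .fixtures$models
}
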
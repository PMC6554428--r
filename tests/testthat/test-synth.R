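test_that("background generation has the contracted shape, determinism and zero cases", {
  cfg <- synthConfig(duration_s = 1.5, fs = 1000, seed = 7)
  rec <- generateBackground(cfg)
  expect_identical(dim(eegData(rec)), c(12L, 1500L))
  expect_identical(channelNames(rec), bciChannels())

  # bit-identical under the same seed, different under another seed
  expect_identical(eegData(generateBackground(cfg)), eegData(rec))
  cfg2 <- cfg; cfg2@seed <- 8
  expect_false(identical(eegData(generateBackground(cfg2)), eegData(rec)))

  # noise off: only the deterministic mu rhythm on sensorimotor channels
  quiet <- fastConfig(noiseScale = 0)
  recq <- generateBackground(quiet)
  expect_true(all(eegData(recq)[match(c("Oz", "Fp2"), bciChannels()), ] == 0))
  expect_gt(sd(getChannel(recq, "C3")), 0)
  silent <- fastConfig(noiseScale = 0, muAmp = 0)
  expect_true(all(eegData(generateBackground(silent)) == 0))

  expect_error(synthConfig(duration_s = -1), "duration_s")
})

test_that("SSVEP injection adds fundamental and harmonic peaks at Oz only", {
  cfg <- fastConfig(seed = 21, duration_s = 2)
  rec <- generateBackground(cfg)
  out <- injectSSVEP(rec, 12.4, amp = 5, harmonicRatio = 0.5)

  # non-Oz channels bitwise untouched
  others <- setdiff(bciChannels(), "Oz")
  expect_identical(eegData(out)[match(others, bciChannels()), ],
                   eegData(rec)[match(others, bciChannels()), ])

  # spectrum of the added component peaks at 12.4 then 24.8 Hz
  added <- getChannel(out, "Oz") - getChannel(rec, "Oz")
  n <- length(added)
  freqs <- (seq_len(n) - 1) * samplingRate(rec) / n
  mag <- Mod(fft(added))[freqs <= samplingRate(rec) / 2]
  freqs <- freqs[freqs <= samplingRate(rec) / 2]
  ord <- order(mag, decreasing = TRUE)
  expect_lt(abs(freqs[ord[1]] - 12.4), 1 / 2)
  expect_lt(abs(freqs[ord[3]] - 24.8), 1 / 2)  # ord[2] is 12.4's neighbor bin

  # amp = 0 leaves the recording unchanged
  expect_identical(eegData(injectSSVEP(rec, 12.4, 0)), eegData(rec))
  expect_error(injectSSVEP(rec, 100, 5), "fs/4")
  noOz <- EEGRecording(matrix(0, 1, 100), "C3", 250)
  expect_error(injectSSVEP(noOz, 12.4, 5), "missing channel")
})

test_that("ERD injection lateralizes mu-band power as imagined-hand contralaterality", {
  cfg <- fastConfig(seed = 31, duration_s = 2)
  rec <- generateBackground(cfg)
  out <- injectMIERD(rec, "left", depth = 0.8)

  bandVar <- function(r, chans) {
    f <- bandpassFilter(r, 9, 12)
    mean(apply(eegData(f)[match(chans, channelNames(r)), ], 1, var))
  }
  right <- hemisphereChannels("right")
  left <- hemisphereChannels("left")
  # left-hand imagery: right (contralateral) hemisphere mu suppressed
  expect_lt(bandVar(out, right), bandVar(out, left))
  # and the mirror image for right-hand imagery
  out2 <- injectMIERD(rec, "right", depth = 0.8)
  expect_lt(bandVar(out2, left), bandVar(out2, right))

  expect_identical(eegData(injectMIERD(rec, "left", 0)), eegData(rec))
  expect_error(injectMIERD(rec, "up", 0.5))
  expect_error(injectMIERD(rec, "left", 1.5), "0, 1")
})

test_that("blink injection subtracts clean troughs at Fp2 only", {
  cfg <- fastConfig(noiseScale = 0, muAmp = 0)
  rec <- generateBackground(cfg)
  # centers on the sample grid (fs = 250) so each trough is a unique minimum
  out <- injectBlinks(rec, c(0.3, 1.06), depth = 100, width_s = 0.2)

  fp2 <- getChannel(out, "Fp2")
  fs <- samplingRate(out)
  # two local minima below -depth/2, at the injected times
  mins <- which(diff(sign(diff(fp2))) > 0) + 1L
  deep <- mins[fp2[mins] < -50]
  expect_length(deep, 2L)
  expect_equal((deep - 1) / fs, c(0.3, 1.06), tolerance = 0.01)

  expect_identical(getChannel(out, "Oz"), getChannel(rec, "Oz"))
  expect_identical(eegData(injectBlinks(rec, numeric(0), 100)), eegData(rec))
  expect_error(injectBlinks(rec, c(0.3, 0.35), 100, width_s = 0.2),
               "overlap")
  expect_error(injectBlinks(rec, 5, 100), "within the recording")
})

test_that("injections on disjoint channels commute exactly", {
  rec <- generateBackground(fastConfig(seed = 41))
  a <- injectBlinks(injectSSVEP(rec, 12.4, 5), 0.75, 100)
  b <- injectSSVEP(injectBlinks(rec, 0.75, 100), 12.4, 5)
  expect_identical(eegData(a), eegData(b))
})

test_that("scripted sessions concatenate spans with a faithful truth track", {
  cfg <- fastConfig(seed = 51)
  ses <- generateSession(data.frame(intent = c("left", "blink", "idle"),
                                    duration_s = c(3, 2, 1)), cfg)
  expect_equal(duration(ses$recording), 6)
  expect_equal(ses$truth$onset_s, c(0, 3, 5))
  expect_identical(unique(ses$sampleIntent[1:750]), "left")
  expect_length(ses$sampleIntent, nSamples(ses$recording))

  # blink pulses appear only inside the blink span
  fp2 <- getChannel(ses$recording, "Fp2")
  idx <- which(fp2 < -cfg@blinkDepth / 2)
  expect_true(all(idx / samplingRate(ses$recording) > 3 &
                  idx / samplingRate(ses$recording) < 5))

  # determinism and error cases
  ses2 <- generateSession(ses$truth[, c("intent", "duration_s")], cfg)
  expect_identical(eegData(ses$recording), eegData(ses2$recording))
  expect_error(generateSession(data.frame(), cfg), "empty")
  expect_error(generateSession(data.frame(intent = "fly", duration_s = 1),
                               cfg), "unknown intent")
})
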
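test_that("band-pass keeps in-band tones and rejects out-of-band tones", {
  fs <- 250
  tt <- (0:(4 * fs - 1)) / fs
  mk <- function(f) EEGRecording(matrix(sin(2 * pi * f * tt), 1), "C3", fs)

  # 10 Hz tone through the mu band: amplitude preserved within 5%
  y10 <- getChannel(bandpassFilter(mk(10), 9, 12), "C3")
  core <- seq(fs, 3 * fs)  # avoid edges for the amplitude estimate
  expect_equal(max(abs(y10[core])), 1, tolerance = 0.05)

  # 50 Hz tone: attenuated by more than 20 dB
  y50 <- getChannel(bandpassFilter(mk(50), 9, 12), "C3")
  expect_lt(max(abs(y50[core])), 0.1)

  # DC offset removed by the 0.3-30 Hz blink band
  dc <- EEGRecording(matrix(7, 1, 4 * fs), "Fp2", fs)
  expect_equal(mean(getChannel(bandpassFilter(dc, 0.3, 30), "Fp2")), 0,
               tolerance = 0.05)

  expect_error(bandpassFilter(mk(10), 12, 9), "invalid band")
  expect_error(bandpassFilter(mk(10), 9, 200), "invalid band")
})

test_that("band-pass filtering is linear", {
  fs <- 250
  set.seed(61)
  x <- matrix(rnorm(2 * fs), 1); y <- matrix(rnorm(2 * fs), 1)
  f <- function(m) eegData(bandpassFilter(EEGRecording(m, "C3", fs), 5, 40))
  expect_equal(f(2 * x + 3 * y), 2 * f(x) + 3 * f(y), tolerance = 1e-9)
})

test_that("CAR removes the subset mean and leaves other channels untouched", {
  fs <- 250
  set.seed(62)
  rec <- generateBackground(fastConfig(seed = 62))
  out <- carFilter(rec)

  idx <- match(miChannels(), channelNames(rec))
  # column sums of the subset vanish at every sample
  expect_equal(max(abs(colSums(eegData(out)[idx, ]))), 0, tolerance = 1e-10)
  expect_identical(getChannel(out, "Oz"), getChannel(rec, "Oz"))
  expect_identical(getChannel(out, "Fp2"), getChannel(rec, "Fp2"))

  # identical signal on all subset channels is annihilated
  same <- EEGRecording(matrix(rep(rnorm(100), each = 10), 10),
                       miChannels(), fs)
  expect_equal(max(abs(eegData(carFilter(same)))), 0, tolerance = 1e-12)

  # idempotent on its subset
  expect_equal(eegData(carFilter(out)), eegData(out), tolerance = 1e-12)
  expect_error(carFilter(rec, c("C3", "Pz")), "missing channel")
})

test_that("window stream follows the 1.5 s / 1 s online cadence", {
  rec <- generateBackground(fastConfig(duration_s = 4.5, seed = 63))
  wins <- windowStream(rec)
  expect_length(wins, 4L)
  expect_equal(vapply(wins, onset, 0), c(0, 1, 2, 3))
  expect_true(all(vapply(wins, nSamples, 0L) == round(1.5 * 250)))

  # consecutive windows share exactly round(0.5 * fs) samples
  shared <- eegData(wins[[1]])[, (250 + 1):375]
  expect_identical(shared, eegData(wins[[2]])[, 1:125])

  expect_length(windowStream(generateBackground(fastConfig(1.5))), 1L)
  expect_length(windowStream(generateBackground(fastConfig(1.0))), 0L)
})
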
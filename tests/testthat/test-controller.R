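test_that("command payloads carry the fixed flight parameters", {
  lf <- commandPayload("LEFT_FORWARD")
  expect_equal(c(lf$yaw_deg, lf$forward_mps, lf$vertical_mps),
               c(-42, 0.25, 0))
  rf <- commandPayload("RIGHT_FORWARD")
  expect_equal(c(rf$yaw_deg, rf$forward_mps, rf$vertical_mps),
               c(42, 0.25, 0))
  expect_equal(commandPayload("RISE")$vertical_mps, 0.2)
  expect_equal(commandPayload("FALL")$vertical_mps, -0.3)
  hv <- commandPayload("HOVER_SWITCH")
  expect_equal(c(hv$yaw_deg, hv$forward_mps, hv$vertical_mps), c(0, 0, 0))
  expect_error(commandPayload("BARREL_ROLL"))
})

test_that("a step dispatches blink first, then the active mode", {
  models <- fastModels()
  cfg <- fastConfig(seed = 110)

  blinkWin <- EpochWindow(injectBlinks(generateBackground(cfg),
                                       c(0.375, 1.125), cfg@blinkDepth), 0)
  st <- controllerStep(blinkWin, "MI", models)
  expect_equal(st$command$kind, "HOVER_SWITCH")
  expect_equal(st$mode, "SSVEP")
  st2 <- controllerStep(blinkWin, "SSVEP", models)
  expect_equal(st2$mode, "MI")
  # refractory stride ignores the blink and decodes the mode instead
  st3 <- controllerStep(blinkWin, "SSVEP", models, refractory = TRUE)
  expect_true(st3$command$kind %in% c("RISE", "FALL"))
  expect_equal(st3$mode, "SSVEP")

  riseWin <- EpochWindow(injectSSVEP(generateBackground(cfg), 12.4,
                                     cfg@ssvepAmp, 0.5), 0)
  st4 <- controllerStep(riseWin, "SSVEP", models)
  expect_equal(st4$command$kind, "RISE")

  leftWin <- EpochWindow(injectMIERD(generateBackground(cfg), "left",
                                     cfg@erdDepth), 0)
  st5 <- controllerStep(leftWin, "MI", models)
  expect_equal(st5$command$kind, "LEFT_FORWARD")
  expect_equal(st5$mode, "MI")
})

test_that("session decoding emits one command per stride and toggles on blinks only", {
  models <- fastModels()
  cfg <- fastConfig(seed = 111)
  script <- data.frame(intent = c("f12.4", "blink", "left", "blink", "f18"),
                       duration_s = c(3, 2, 3, 2, 3))
  ses <- generateSession(script, cfg)
  log <- runSession(ses$recording, models)

  # cadence: floor((13 - 1.5) / 1) + 1 commands
  expect_equal(nrow(log), 12L)
  expect_equal(log$onset_s, 0:11)

  # mode changes exactly at HOVER_SWITCH emissions
  switches <- which(log$command == "HOVER_SWITCH")
  modeChanges <- which(log$mode_before[-1] != log$mode_before[-nrow(log)])
  expect_equal(modeChanges, switches)
  expect_equal(length(switches), 2L)

  # determinism: identical log on a second run
  expect_identical(runSession(ses$recording, models), log)

  # short recordings give an empty log
  empty <- runSession(generateBackground(fastConfig(1.2)), models)
  expect_equal(nrow(empty), 0L)
})

test_that("scripted intents are recovered on non-transition strides", {
  models <- fastModels()
  cfg <- fastConfig(seed = 112)
  script <- data.frame(
    intent = c("f12.4", "blink", "left", "right", "blink", "f18"),
    duration_s = c(4, 2, 4, 4, 2, 4))
  ses <- generateSession(script, cfg)
  log <- runSession(ses$recording, models)

  expected <- c("f12.4" = "RISE", "f18" = "FALL",
                "left" = "LEFT_FORWARD", "right" = "RIGHT_FORWARD")
  spanEnd <- ses$truth$onset_s + ses$truth$duration_s
  hits <- 0L; total <- 0L
  for (i in seq_len(nrow(log))) {
    o <- log$onset_s[i]
    j <- which(ses$truth$onset_s <= o & spanEnd >= o + 1.5)
    if (length(j) == 1L && ses$truth$intent[j] %in% names(expected)) {
      total <- total + 1L
      hits <- hits + (log$command[i] == expected[[ses$truth$intent[j]]])
    }
  }
  expect_gte(total, 10L)
  expect_gte(hits / total, 0.9)
})
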
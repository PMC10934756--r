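test_that("generators are pure functions of parameters and seed", {
  a <- genEyeImage("OPEN_OR_HALF", seed = 7)
  b <- genEyeImage("OPEN_OR_HALF", seed = 7)
  expect_identical(imageRaster(a), imageRaster(b))
  e1 <- genEegEpoch("DROWSY", seed = 9)
  e2 <- genEegEpoch("DROWSY", seed = 9)
  expect_identical(eegSamples(e1), eegSamples(e2))
  scen <- SessionScenario(10, blinkTimes = c(2, 6), seed = 3)
  g1 <- genEogStream(scen); g2 <- genEogStream(scen)
  expect_identical(channelMatrix(g1$stream), channelMatrix(g2$stream))
  # the caller's RNG stream is untouched
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(genEyeImage("CLOSED", seed = 4))
  expect_identical(stats::runif(1), before)
})

test_that("eye-image classes are separable by construction at zero noise", {
  open <- genEyeImage("OPEN_OR_HALF", seed = 1, noiseSd = 0)
  closed <- genEyeImage("CLOSED", seed = 1, noiseSd = 0)
  profO <- rowMeans(imageRaster(open))
  profC <- rowMeans(imageRaster(closed))
  expect_gt(max(abs(profO - profC)), 0.05)  # vertical profiles differ
  expect_error(genEyeImage("OPEN_OR_HALF", noiseSd = -1), ">= 0")
  expect_error(genEyeImage("squint"), "state")
})

test_that("the corpus reproduces the 200-image experimental design", {
  corpus <- fixtureCorpus()
  expect_length(corpus, 200)
  labels <- vapply(corpus, imageLabel, character(1))
  expect_equal(unname(table(labels)["OPEN_OR_HALF"]), 100, ignore_attr = TRUE)
  sp <- fixtureSplit()
  expect_length(sp$train, 140)  # 70 + 70 for training
  expect_length(sp$test, 60)    # the rest kept for testing
  expect_length(genEyeCorpus(1, seed = 2), 2)
  expect_error(genEyeCorpus(0), ">= 1")
})

test_that("landmark generation spans closed to open with exact EAR values", {
  lm0 <- genLandmarks(0)[[1]]
  expect_equal(computeEAR(lm0), 0)
  lm1 <- genLandmarks(1, cornerDist = 4, maxLidGap = 2)[[1]]
  expect_equal(lm1["p2", ], c(x = 1, y = -1))  # offsets 1 and 3, gap 2
  expect_equal(lm1["p3", ], c(x = 3, y = -1))
  expect_equal(computeEAR(lm1), 0.5)
  ramp <- vapply(genLandmarks(seq(0.1, 1, by = 0.1)), computeEAR, numeric(1))
  expect_true(all(diff(ramp) > 0))
  expect_error(genLandmarks(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("EOG generation round-trips through the detector", {
  scen <- SessionScenario(20, blinkTimes = c(3, 8, 15),
                          snr = c(eog = Inf, eeg = 5, image = 20), seed = 5)
  g <- genEogStream(scen)
  ev <- detectBlinkSignature(detectStreamPulses(preprocessEog(g$stream)))
  expect_equal(nrow(ev), 3)
  expect_true(all(abs(sort(ev$time_s) - c(3, 8, 15)) < 0.05))
  # no events, zero noise: flat-zero channels
  quiet <- genEogStream(SessionScenario(5, snr = c(eog = Inf, eeg = 5,
                                                   image = 20), seed = 1))
  expect_equal(max(abs(channelMatrix(quiet$stream))), 0)
  # distractor-only stream yields no blinks
  distr <- genEogStream(
    SessionScenario(10, snr = c(eog = Inf, eeg = 5, image = 20), seed = 2),
    distractors = data.frame(time = c(2, 5, 8), kind = "S1"))
  evd <- detectBlinkSignature(detectStreamPulses(preprocessEog(distr$stream)))
  expect_equal(nrow(evd), 0)
  expect_error(genEogStream(SessionScenario(5, blinkTimes = 10, seed = 1)),
               "within")
})

test_that("EEG generation round-trips through the classifier", {
  expect_equal(classifyEpoch(computePsd(genEegEpoch("DROWSY", seed = 61))),
               "DROWSY")
  expect_equal(classifyEpoch(computePsd(genEegEpoch("ALERT", seed = 61))),
               "ALERT")
  pk <- alphaPeak(computePsd(genEegEpoch("DROWSY", seed = 62)))
  expect_gte(pk$prominenceRatio, 3)
  expect_error(genEegEpoch("DROWSY", sampleRate = 50), "60 Hz")
  expect_error(genEegEpoch("DROWSY", duration = 1), "2 s")
})

test_that("a generated session is internally consistent and file round-trips", {
  scen <- SessionScenario(20, blinkTimes = c(2, 6, 17),
                          drowsyWindows = matrix(c(9, 14), 1), seed = 12)
  sess <- genSession(scen)
  expect_length(sess$landmarks, 20 * 25)
  ear <- earSeriesFromLandmarks(sess$landmarks)
  # drowsy stretch is closed, alert stretch open
  vals <- earValues(ear)
  tt <- (seq_along(vals) - 0.5) / 25
  expect_lt(max(vals[tt > 9.5 & tt < 13.5]), 0.2)
  expect_gt(min(vals[tt > 15 & tt < 16.5]), 0.2)
  dir <- withr::local_tempdir()
  writeSession(sess, dir)
  back <- loadSession(dir)
  expect_length(back$landmarks, length(sess$landmarks))
  expect_equal(back$frameRate, 25)
  expect_equal(vapply(back$images, imageLabel, character(1)),
               vapply(sess$images, imageLabel, character(1)))
  expect_equal(channelMatrix(back$eog$stream),
               channelMatrix(sess$eog$stream), tolerance = 1e-9)
  expect_equal(eegSamples(back$eeg), eegSamples(sess$eeg), tolerance = 1e-9)
  expect_equal(back$groundTruth$blink_times, c(2, 6, 17))
})
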
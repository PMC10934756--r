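test_that("preprocessing removes DC, keeps in-band sinusoids, rejects bad bands", {
  fs <- 250
  t <- seq(0, 10, by = 1 / fs)[-1]
  flat <- EogStream(rep(3, length(t)), rep(-2, length(t)), rep(0.5, length(t)),
                    sampleRate = fs)
  out <- preprocessEog(flat)
  expect_lt(max(abs(channelMatrix(out))), 1e-6)
  sine <- sin(2 * pi * 5 * t)  # 5 Hz, well inside 0.5-20 Hz
  st <- preprocessEog(EogStream(sine, sine, sine, sampleRate = fs))
  mid <- channelMatrix(st)[500:2000, 1]
  expect_lt(abs(max(mid) - 1), 0.05)  # passband amplitude within 5%
  expect_error(preprocessEog(flat, band = c(0.5, 200)), "Nyquist")
})

test_that("matched filtering finds injected pulses with the right kind and time", {
  fs <- 250
  tpl <- eogTemplates(fs)
  n <- 5 * fs
  halfWidth <- (length(tpl$S2) - 1) / 2 / fs
  set.seed(21)
  for (kind in c("S1", "S2")) {
    x <- stats::rnorm(n, 0, 0.1)  # SNR 10
    at <- round(1.0 * fs)
    idx <- at - (length(tpl[[kind]]) - 1) %/% 2 + seq_along(tpl[[kind]]) - 1
    x[idx] <- x[idx] + tpl[[kind]]
    p <- detectPulses(x, fs, tpl, minCorr = 0.7)
    expect_equal(nrow(p), 1)
    expect_equal(p$kind, kind)
    expect_lt(abs(p$time - 1.0), halfWidth)
  }
  # pure low-amplitude noise: nothing above threshold
  expect_equal(nrow(detectPulses(stats::rnorm(n, 0, 0.05), fs, tpl)), 0)
  expect_error(detectPulses(stats::rnorm(10), fs, tpl), "longer")
})

test_that("pulse detections never overlap within a channel", {
  fs <- 250
  scen <- SessionScenario(30, blinkTimes = seq(2, 28, by = 2), seed = 8)
  g <- genEogStream(scen)
  pulses <- detectStreamPulses(preprocessEog(g$stream))
  span <- length(eogTemplates(fs)$S2) / fs
  for (ch in pulses) {
    if (nrow(ch) > 1) expect_true(all(diff(ch$time) >= span - 1e-9))
  }
})

test_that("the blink signature S2/S1/S1 is required for an event", {
  mk <- function(t, kind) data.frame(time = t, kind = kind,
                                     score = rep(0.9, length(t)))
  # matching triple within tolerance
  ev <- detectBlinkSignature(list(EOG1 = mk(2.00, "S2"), EOG2 = mk(2.01, "S1"),
                                  EOG3 = mk(1.99, "S1")), tolerance = 0.05)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$time_s, 2.00)
  expect_equal(ev$source, "EOG")
  # S1 on all three channels is some other eye movement, not a blink
  ev2 <- detectBlinkSignature(list(EOG1 = mk(2, "S1"), EOG2 = mk(2, "S1"),
                                   EOG3 = mk(2, "S1")), tolerance = 0.05)
  expect_equal(nrow(ev2), 0)
  # outside tolerance: no event
  ev3 <- detectBlinkSignature(list(EOG1 = mk(2, "S2"), EOG2 = mk(2.2, "S1"),
                                   EOG3 = mk(2, "S1")), tolerance = 0.05)
  expect_equal(nrow(ev3), 0)
  # empty input
  expect_equal(nrow(detectBlinkSignature(list())), 0)
})

test_that("round-trip recovery is exact and matches the exhaustive matcher", {
  tol <- 0.05
  for (seed in 1:8) {
    nBlinks <- 2 + seed %% 4
    blinks <- sort(2 + (seq_len(nBlinks) - 1) * 4 +
                     withr::with_seed(seed, stats::runif(nBlinks, -0.5, 0.5)))
    scen <- SessionScenario(4 * nBlinks + 4, blinkTimes = blinks,
                            snr = c(eog = 5, eeg = 5, image = 20),
                            seed = seed)
    distr <- data.frame(time = blinks + 2,
                        kind = rep(c("S1", "S2"), length.out = nBlinks))
    g <- genEogStream(scen, distractors = distr)
    pulses <- detectStreamPulses(preprocessEog(g$stream))
    ev <- detectBlinkSignature(pulses, tolerance = tol)
    expect_equal(nrow(ev), nBlinks)  # precision = recall = 1
    expect_true(all(abs(sort(ev$time_s) - blinks) <= tol))
    # greedy matcher agrees with exhaustive triple enumeration
    t1 <- pulses$EOG1$time[pulses$EOG1$kind == "S2"]
    t2 <- pulses$EOG2$time[pulses$EOG2$kind == "S1"]
    t3 <- pulses$EOG3$time[pulses$EOG3$kind == "S1"]
    expect_equal(nrow(ev), oracleMaxTriples(t1, t2, t3, tol))
  }
})

test_that("event count is invariant to a uniform time shift", {
  scen <- SessionScenario(20, blinkTimes = c(3, 8, 15), seed = 5)
  g <- genEogStream(scen)
  ev <- detectBlinkSignature(detectStreamPulses(preprocessEog(g$stream)))
  shift <- 2.0
  ch <- channelMatrix(g$stream)
  pad <- matrix(0, round(shift * 250), 3)
  shifted <- EogStream(c(pad[, 1], ch[, 1]), c(pad[, 2], ch[, 2]),
                       c(pad[, 3], ch[, 3]), sampleRate = 250)
  ev2 <- detectBlinkSignature(detectStreamPulses(preprocessEog(shifted)))
  expect_equal(nrow(ev2), nrow(ev))
  expect_equal(sort(ev2$time_s), sort(ev$time_s) + shift, tolerance = 0.02)
})

test_that("EOG channel score peaks at the baseline rate and falls linearly", {
  atRate <- function(n) data.frame(time_s = seq_len(n))
  expect_equal(eogChannelScore(atRate(15), window = 60), 1)       # baseline
  expect_equal(eogChannelScore(atRate(0), window = 60), 0)        # no blinks
  expect_lt(eogChannelScore(atRate(30), window = 60), 1)          # elevated
  expect_equal(eogChannelScore(atRate(30), window = 60), 0)       # 2x -> 0
  expect_equal(eogChannelScore(atRate(10), window = 60), 1 - 5 / 15)
  expect_error(eogChannelScore(atRate(5), window = -1), "positive")
})

test_that("EOG streams round-trip through CSV", {
  scen <- SessionScenario(5, blinkTimes = c(2), seed = 4)
  g <- genEogStream(scen)
  p <- withr::local_tempfile(fileext = ".csv")
  writeEogCsv(g$stream, p)
  back <- readEogCsv(p)
  expect_equal(sampleRate(back), 250)
  expect_equal(channelMatrix(back), channelMatrix(g$stream),
               tolerance = 1e-9)
})
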
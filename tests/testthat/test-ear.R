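test_that("euclidean distance matches hand-computed cases and is symmetric", {
  expect_equal(euclideanDistance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclideanDistance(c(1, 1), c(1, 1)), 0)
  expect_equal(euclideanDistance(c(2, -1), c(-1, 3)), 5)  # sqrt(9 + 16)
  expect_equal(euclideanDistance(c(2, -1), c(-1, 3)),
               euclideanDistance(c(-1, 3), c(2, -1)))
  expect_error(euclideanDistance(c(NA, 0), c(1, 1)), "finite")
  expect_error(euclideanDistance(c(Inf, 0), c(1, 1)), "finite")
})

test_that("EAR evaluates the landmark ratio correctly", {
  hexagon <- eyeLandmarks(c(0, 0), c(1, 1), c(3, 1), c(4, 0),
                          c(3, -1), c(1, -1))
  expect_equal(computeEAR(hexagon), 0.5)  # (2 + 2) / (2 * 4)
  expect_equal(computeEAR(hexagon * 10), 0.5)  # scale invariance
  closed <- eyeLandmarks(c(0, 0), c(1, 0.3), c(3, 0.3), c(4, 0),
                         c(3, 0.3), c(1, 0.3))  # p2 = p6, p3 = p5
  expect_equal(computeEAR(closed), 0)
  expect_error(eyeLandmarks(c(1, 2), c(1, 1), c(3, 1), c(1, 2),
                            c(3, -1), c(1, -1)), "degenerate")
})

test_that("EAR is invariant under rigid motion and scaling, monotone in lid gap", {
  set.seed(101)
  for (rep in 1:1000) {
    lm <- matrix(stats::runif(12, -10, 10), 6, 2)
    if (all(lm[1, ] == lm[4, ])) next
    base <- computeEAR(lm)
    theta <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    s <- stats::runif(1, 0.1, 10)
    shift <- matrix(stats::runif(2, -50, 50), 6, 2, byrow = TRUE)
    expect_equal(computeEAR(s * lm %*% R + shift), base, tolerance = 1e-9)
  }
  # parametric openness sweep: EAR non-decreasing in lid separation
  sweep <- vapply(genLandmarks(seq(0, 1, by = 0.05)), computeEAR, numeric(1))
  expect_true(all(diff(sweep) > 0))
})

test_that("threshold segmentation matches the frame-by-frame oracle", {
  expect_equal(segmentEarSeries(EarSeries(c(.3, .3, .05, .05, .3)), 0.15),
               data.frame(start = 2L, end = 4L),
               ignore_attr = TRUE)
  expect_equal(nrow(segmentEarSeries(EarSeries(c(.3, .3, .3)), 0.15)), 0)
  expect_equal(segmentEarSeries(EarSeries(c(.05, .05)), 0.15),
               data.frame(start = 0L, end = 2L), ignore_attr = TRUE)
  # equality at threshold counts as open
  expect_equal(nrow(segmentEarSeries(EarSeries(c(0.15, 0.15)), 0.15)), 0)
  expect_error(segmentEarSeries(EarSeries(numeric()), 0.15), "empty")
  set.seed(202)
  for (rep in 1:50) {
    vals <- stats::runif(stats::rpois(1, 40) + 1, 0, 0.4)
    got <- segmentEarSeries(EarSeries(vals), 0.2)
    ora <- oracleSegments(vals, 0.2)
    expect_equal(got, ora, ignore_attr = TRUE)
    # intervals disjoint, sorted, union = sub-threshold frames
    if (nrow(got) > 1)
      expect_true(all(got$start[-1] >= got$end[-nrow(got)]))
    covered <- unlist(mapply(function(s, e) seq(s, e - 1),
                             got$start, got$end, SIMPLIFY = FALSE))
    expect_setequal(covered, which(vals < 0.2) - 1L)
  }
})

test_that("blink events obey the duration gate and midpoint timing", {
  vals <- rep(0.3, 30); vals[11:13] <- 0.05  # frames 10-12 (0-based)
  ev <- extractBlinkEvents(EarSeries(vals, 25), 0.15)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$time_s, 11.5 / 25)
  expect_equal(ev$duration_s, 0.12)
  expect_equal(ev$source, "EAR")
  # 40 closed frames = 1.6 s exceeds maxDur: a prolonged closure, not a blink
  long <- rep(0.3, 60); long[11:50] <- 0.05
  expect_equal(nrow(extractBlinkEvents(EarSeries(long, 25), 0.15)), 0)
  expect_equal(nrow(extractBlinkEvents(EarSeries(rep(0.3, 20), 25), 0.15)), 0)
  expect_error(extractBlinkEvents(EarSeries(vals, 25), 0.15,
                                  minDur = 0.5, maxDur = 0.2), "minDur")
})

test_that("blink statistics report rate and interval moments", {
  ev3 <- data.frame(time_s = c(1, 2, 3))
  st <- blinkStatistics(ev3, window = 60)
  expect_equal(st$rate, 3)
  expect_equal(st$meanInterval, 1)
  st12 <- blinkStatistics(data.frame(time_s = seq_len(12)), window = 60)
  expect_equal(st12$rate, 12)
  st0 <- blinkStatistics(data.frame(time_s = numeric()), window = 60)
  expect_equal(st0$rate, 0)
  expect_true(is.na(st0$meanInterval))
  expect_error(blinkStatistics(ev3, window = -5), "positive")
})

test_that("EAR channel score is the open fraction and complements closure", {
  expect_equal(earChannelScore(EarSeries(rep(0.3, 10))), 1)
  expect_equal(earChannelScore(EarSeries(rep(0.05, 10))), 0)
  expect_equal(earChannelScore(EarSeries(c(rep(0.3, 5), rep(0.05, 5)))), 0.5)
  set.seed(303)
  for (rep in 1:20) {
    vals <- stats::runif(50, 0, 0.4)
    s <- EarSeries(vals)
    closedFrames <- sum(vals < 0.2) / length(vals)
    expect_equal(earChannelScore(s) + closedFrames, 1)
  }
})

test_that("landmark and EAR series round-trip through CSV", {
  frames <- genLandmarks(c(0.2, 0.8, 1))
  p <- withr::local_tempfile(fileext = ".csv")
  writeLandmarksCsv(frames, p)
  back <- readLandmarksCsv(p)
  expect_equal(lapply(back, unname), lapply(frames, unname))
  s <- earSeriesFromLandmarks(frames)
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeEarSeriesCsv(s, p2)
  expect_equal(earValues(readEarSeriesCsv(p2)), earValues(s))
})
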
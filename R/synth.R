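# Seeded synthetic generators for every input modality. Each generator is a
# pure function of (parameters, seed): randomness is drawn under a locally
# fixed RNG state, so the same call always returns the same data and the
# caller's RNG stream is untouched. At zero noise every generated modality
# is classified correctly by its detection module (round-trip identity), so
# detector failures in tests are attributable to the detector.

#' Generate a schematic 51 x 51 eye image
#'
#' Open (or half-open) eyes are rendered as an almond-shaped bright sclera
#' aperture containing a dark iris/pupil disk on a mid-gray skin background;
#' closed eyes as a narrow dark horizontal lid crease. Seeded Gaussian noise
#' is added and intensities clipped to [0, 1]. The rendering is deliberately
#' schematic: the classifiers consume heavily down-sampled rasters where
#' only coarse structure survives, so coarse structure is what the generator
#' provides.
#'
#' @param state "OPEN_OR_HALF" or "CLOSED".
#' @param seed integer seed.
#' @param noiseSd additive noise standard deviation, >= 0 (default 0.05).
#' @return a labeled \linkS4class{EyeImage}.
#' @export
genEyeImage <- function(state, seed = 1L, noiseSd = 0.05) {
  if (!state %in% c("OPEN_OR_HALF", "CLOSED"))
    stop("state must be OPEN_OR_HALF or CLOSED")
  if (!is.finite(noiseSd) || noiseSd < 0) stop("noiseSd must be >= 0")
  n <- 51L
  cx <- (n + 1) / 2
  xs <- matrix(rep(seq_len(n), each = n), n)   # column index
  ys <- matrix(rep(seq_len(n), times = n), n)  # row index
  img <- withSeed(seed, {
    skin <- 0.75
    base <- matrix(skin, n, n)
    # mild seeded geometry variation keeps the classes non-trivial
    apH <- stats::runif(1, 9, 12)    # aperture half-height
    apW <- stats::runif(1, 20, 24)   # aperture half-width
    irisR <- stats::runif(1, 6, 8)
    if (state == "OPEN_OR_HALF") {
      aperture <- ((xs - cx) / apW)^2 + ((ys - cx) / apH)^2 <= 1
      base[aperture] <- 0.95
      pupil <- (xs - cx)^2 + (ys - cx)^2 <= irisR^2
      base[pupil & aperture] <- 0.15
    } else {
      crease <- abs(ys - cx) <= 1.5 & abs(xs - cx) <= apW
      base[crease] <- 0.25
      lash <- abs(ys - cx) > 1.5 & abs(ys - cx) <= 3 & abs(xs - cx) <= apW
      base[lash] <- 0.55
    }
    if (noiseSd > 0)
      base <- base + matrix(stats::rnorm(n * n, 0, noiseSd), n)
    clip01(base)
  })
  EyeImage(img, label = state, sourceSize = c(n, n))
}

#' Generate a balanced labeled eye-image corpus
#'
#' \code{nPerClass} open/half-open and \code{nPerClass} closed images under
#' one master seed (per-image sub-seeds). The default of 100 per class
#' reproduces the 200-image experimental design, from which 70 + 70 images
#' train the networks and the remaining 60 are held out for testing.
#'
#' @param nPerClass images per class, >= 1 (default 100).
#' @param seed master seed.
#' @param noiseSd per-image noise level.
#' @return list of 2 * nPerClass labeled \linkS4class{EyeImage}s,
#'   alternating classes.
#' @export
genEyeCorpus <- function(nPerClass = 100L, seed = 1L, noiseSd = 0.05) {
  if (!is.finite(nPerClass) || nPerClass < 1) stop("nPerClass must be >= 1")
  states <- rep(c("OPEN_OR_HALF", "CLOSED"), nPerClass)
  lapply(seq_along(states), function(i)
    genEyeImage(states[i], seed = subSeed(seed, i), noiseSd = noiseSd))
}

#' Split a corpus into the 70 + 70 training and 60 test design
#'
#' Takes the first \code{nTrainPerClass} images of each class for training
#' and leaves the rest as the holdout, preserving balance.
#'
#' @param corpus list of labeled \linkS4class{EyeImage}s.
#' @param nTrainPerClass training images per class (default 70).
#' @return list with \code{train} and \code{test} image lists.
#' @export
splitEyeCorpus <- function(corpus, nTrainPerClass = 70L) {
  labels <- vapply(corpus, imageLabel, character(1))
  train <- integer()
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < nTrainPerClass)
      stop("not enough images of class ", cl)
    train <- c(train, idx[seq_len(nTrainPerClass)])
  }
  list(train = corpus[sort(train)], test = corpus[-sort(train)])
}

#' Generate per-frame eye landmarks from an openness trajectory
#'
#' Eye corners sit at (0, 0) and (cornerDist, 0); the upper-lid points p2/p3
#' and lower-lid points p6/p5 sit at horizontal offsets 1/4 and 3/4 of the
#' eye width, displaced vertically by openness * maxLidGap / 2 above and
#' below the corner line (image coordinates, y down). The EAR of frame i is
#' then openness_i * maxLidGap / (2 cornerDist) * 2, strictly increasing in
#' openness.
#'
#' @param openness numeric vector in [0, 1], one value per frame.
#' @param cornerDist horizontal eye width in pixels (default 4).
#' @param maxLidGap lid separation at openness 1, in pixels (default 2).
#' @return list of 6 x 2 landmark matrices.
#' @export
genLandmarks <- function(openness, cornerDist = 4, maxLidGap = 2) {
  if (any(!is.finite(openness)) || any(openness < 0 | openness > 1))
    stop("openness values must lie in [0, 1]")
  lapply(openness, function(o) {
    g <- o * maxLidGap / 2
    eyeLandmarks(c(0, 0),
                 c(cornerDist / 4, -g), c(3 * cornerDist / 4, -g),
                 c(cornerDist, 0),
                 c(3 * cornerDist / 4, g), c(cornerDist / 4, g))
  })
}

#' Openness trajectory for a session scenario
#'
#' High openness (0.9) while alert, near-closed (0.05) inside drowsy
#' windows, with a 3-frame dip to 0 at each blink. Small seeded jitter keeps
#' frames from being identical.
#'
#' @param scenario a \linkS4class{SessionScenario}.
#' @param frameRate frames per second (default 25).
#' @return numeric openness vector, one value per frame.
#' @export
opennessTrajectory <- function(scenario, frameRate = 25) {
  nFrames <- round(scenario@duration * frameRate)
  tt <- (seq_len(nFrames) - 0.5) / frameRate
  open <- rep(0.9, nFrames)
  w <- scenario@drowsyWindows
  for (i in seq_len(nrow(w)))
    open[tt >= w[i, 1] & tt < w[i, 2]] <- 0.05
  for (b in scenario@blinkTimes) {
    f0 <- round(b * frameRate)
    idx <- intersect(f0 + 0:2, seq_len(nFrames))
    open[idx] <- 0
  }
  jit <- withSeed(subSeed(scenario@seed, 11L),
                  stats::runif(nFrames, -0.05, 0.05))
  clip01(open + jit * (open > 0.5))  # jitter only the open plateau
}

#' Generate a three-channel EOG stream with embedded blink signatures
#'
#' Inserts the blink configuration — an S2 pulse on EOG1 and S1 pulses on
#' EOG2/EOG3 — at every blink time of the scenario, with per-channel timing
#' jitter below half the coincidence tolerance, then adds seeded Gaussian
#' noise at the scenario's EOG SNR (amplitude ratio; \code{Inf} means
#' noise-free). Distractor triples of non-blink configurations (e.g. S1 on
#' all three channels) can be added to exercise signature rejection.
#'
#' @param scenario a \linkS4class{SessionScenario}.
#' @param sampleRate Hz (default 250).
#' @param templates pulse templates (default \code{\link{eogTemplates}}).
#' @param tolerance coincidence tolerance the jitter must respect (s).
#' @param distractors optional data.frame with columns \code{time} and
#'   \code{kind} ("S1" or "S2"): at each row's time, a pulse of that single
#'   kind is placed on all three channels.
#' @return list with \code{stream} (an \linkS4class{EogStream}) and
#'   \code{events} (ground-truth blink times, data.frame \code{time_s}).
#' @export
genEogStream <- function(scenario, sampleRate = 250,
                         templates = eogTemplates(sampleRate),
                         tolerance = 0.05, distractors = NULL) {
  n <- round(scenario@duration * sampleRate)
  span <- max(length(templates$S1), length(templates$S2))
  ch <- matrix(0, n, 3, dimnames = list(NULL, c("EOG1", "EOG2", "EOG3")))
  addPulse <- function(ch, col, tpl, t0) {
    i0 <- round(t0 * sampleRate) - (length(tpl) - 1) %/% 2
    idx <- i0 + seq_along(tpl) - 1L
    ok <- idx >= 1L & idx <= n
    if (!any(ok)) stop("pulse time outside the stream duration")
    ch[idx[ok], col] <- ch[idx[ok], col] + tpl[ok]
    ch
  }
  jitters <- withSeed(subSeed(scenario@seed, 21L), {
    matrix(stats::runif(3 * length(scenario@blinkTimes),
                        -tolerance / 4, tolerance / 4), ncol = 3)
  })
  for (i in seq_along(scenario@blinkTimes)) {
    b <- scenario@blinkTimes[i]
    ch <- addPulse(ch, 1L, templates$S2, b + jitters[i, 1])
    ch <- addPulse(ch, 2L, templates$S1, b + jitters[i, 2])
    ch <- addPulse(ch, 3L, templates$S1, b + jitters[i, 3])
  }
  if (!is.null(distractors) && nrow(distractors)) {
    for (i in seq_len(nrow(distractors))) {
      tpl <- templates[[distractors$kind[i]]]
      for (col in 1:3) ch <- addPulse(ch, col, tpl, distractors$time[i])
    }
  }
  snr <- scenario@snr[["eog"]]
  if (is.finite(snr)) {
    noise <- withSeed(subSeed(scenario@seed, 22L),
                      matrix(stats::rnorm(n * 3, 0, 1 / snr), n))
    ch <- ch + noise
  }
  list(stream = new("EogStream", sampleRate = sampleRate, channels = ch),
       events = data.frame(time_s = scenario@blinkTimes))
}

# 1/f^(alpha/2)-shaped noise via spectral shaping of seeded white noise,
# normalized to unit RMS.
shapedNoise <- function(n, fs, shape) {
  freqs <- seq(0, fs / 2, length.out = n %/% 2L + 1L)
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  gain <- shape(freqs)
  full <- c(gain, rev(gain[2:(n - length(gain) + 1L)]))
  x <- Re(stats::fft(W * full, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Generate a synthetic EEG epoch
#'
#' DROWSY epochs carry a strong oscillation at a seeded frequency in the
#' 10-12 Hz alpha domain over pink-ish background noise; ALERT epochs carry
#' beta-weighted (13-30 Hz) broadband activity over the same background,
#' with no alpha component. SNR is the amplitude ratio of the rhythm to the
#' background.
#'
#' @param state "DROWSY" or "ALERT".
#' @param sampleRate Hz, > 60 (default 128).
#' @param duration s, >= 2 (default 4).
#' @param seed integer seed.
#' @param snr rhythm-to-background amplitude ratio (default 5).
#' @return an \linkS4class{EegEpoch} with attributes \code{state} and
#'   \code{alphaFreq} (the injected frequency, DROWSY only).
#' @export
genEegEpoch <- function(state, sampleRate = 128, duration = 4, seed = 1L,
                        snr = 5) {
  if (!state %in% c("DROWSY", "ALERT")) stop("state must be DROWSY or ALERT")
  if (!is.finite(sampleRate) || sampleRate <= 60)
    stop("sampleRate must exceed 60 Hz")
  if (!is.finite(duration) || duration < 2)
    stop("duration must be at least 2 s")
  n <- round(duration * sampleRate)
  tt <- (seq_len(n) - 1L) / sampleRate
  out <- withSeed(seed, {
    pink <- shapedNoise(n, sampleRate,
                        function(f) 1 / sqrt(pmax(f, 0.5)))
    if (state == "DROWSY") {
      f0 <- stats::runif(1, 10, 12)
      rhythm <- sqrt(2) * sin(2 * pi * f0 * tt + stats::runif(1, 0, 2 * pi))
      list(x = snr * rhythm + pink, alphaFreq = f0)
    } else {
      beta <- shapedNoise(n, sampleRate,
                          function(f) as.numeric(f >= 13 & f <= 30))
      list(x = snr * beta + pink, alphaFreq = NA_real_)
    }
  })
  ep <- EegEpoch(out$x, sampleRate = sampleRate)
  attr(ep, "state") <- state
  attr(ep, "alphaFreq") <- out$alphaFreq
  ep
}

#' Generate a continuous session EEG trace
#'
#' Alpha rhythm inside the scenario's drowsy windows, beta-weighted
#' broadband outside, pink background throughout.
#'
#' @param scenario a \linkS4class{SessionScenario}.
#' @param sampleRate Hz (default 128).
#' @return an \linkS4class{EegEpoch} spanning the whole session, with the
#'   injected alpha frequency as attribute \code{alphaFreq}.
#' @export
genEegSession <- function(scenario, sampleRate = 128) {
  n <- round(scenario@duration * sampleRate)
  tt <- (seq_len(n) - 1L) / sampleRate
  snr <- scenario@snr[["eeg"]]
  withSeed(subSeed(scenario@seed, 31L), {
    pink <- shapedNoise(n, sampleRate, function(f) 1 / sqrt(pmax(f, 0.5)))
    beta <- shapedNoise(n, sampleRate,
                        function(f) as.numeric(f >= 13 & f <= 30))
    f0 <- stats::runif(1, 10, 12)
    alpha <- sqrt(2) * sin(2 * pi * f0 * tt)
    drowsy <- rep(FALSE, n)
    w <- scenario@drowsyWindows
    for (i in seq_len(nrow(w)))
      drowsy[tt >= w[i, 1] & tt < w[i, 2]] <- TRUE
    x <- pink + snr * ifelse(drowsy, alpha, beta)
    ep <- EegEpoch(x, sampleRate = sampleRate)
    attr(ep, "alphaFreq") <- f0
    ep
  })
}

#' Generate a complete multimodal synthetic session
#'
#' One call produces time-aligned inputs for every pipeline stage: per-frame
#' landmarks (and the EAR openness trajectory behind them), per-frame eye
#' images at a reduced image rate, the EOG stream with embedded blink
#' signatures, and the continuous EEG trace. Blinks are suppressed inside
#' drowsy windows by construction of the scenario's blink times.
#'
#' @param scenario a \linkS4class{SessionScenario}.
#' @param frameRate landmark/video frame rate (default 25 fps).
#' @param imageFps eye-image sampling rate (default 5 fps; images are
#'   expensive relative to landmarks).
#' @param eogRate,eegRate signal sampling rates in Hz.
#' @return list with \code{landmarks}, \code{frameRate}, \code{images}
#'   (labeled \linkS4class{EyeImage}s), \code{imageTimes}, \code{eog}
#'   (stream + events), \code{eeg}, and \code{scenario}.
#' @export
genSession <- function(scenario, frameRate = 25, imageFps = 5,
                       eogRate = 250, eegRate = 128) {
  open <- opennessTrajectory(scenario, frameRate)
  lms <- genLandmarks(open)
  nImg <- round(scenario@duration * imageFps)
  imageTimes <- (seq_len(nImg) - 0.5) / imageFps
  imgNoise <- 1 / (2 * scenario@snr[["image"]])
  frameIdx <- pmin(length(open), pmax(1L, round(imageTimes * frameRate)))
  states <- ifelse(open[frameIdx] < 0.5, "CLOSED", "OPEN_OR_HALF")
  images <- lapply(seq_len(nImg), function(i)
    genEyeImage(states[i], seed = subSeed(scenario@seed, 100L + i),
                noiseSd = imgNoise))
  list(landmarks = lms, frameRate = frameRate,
       images = images, imageTimes = imageTimes,
       eog = genEogStream(scenario, sampleRate = eogRate),
       eeg = genEegSession(scenario, sampleRate = eegRate),
       scenario = scenario)
}
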
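# End-to-end orchestration: sliding-window channel scores, fuzzy fusion,
# warning emission. The three evidences arrive at different rates (frames,
# samples, epochs); the pipeline time-aligns them by scoring each modality
# over the same sliding window and fusing the three window scores.

#' Pipeline configuration
#'
#' @param channel1Source which modality feeds fuzzy input 1: "EOG" (blink
#'   rate) or "EEG" (alpha prominence). Both were recorded for the same
#'   purpose; the method choice is a configuration, not a code path change.
#' @param window,hop sliding-window length and spacing in seconds
#'   (defaults 10 and 5; blink-rate statistics need multi-second support).
#'   Requires 0 < hop <= window.
#' @param earThreshold EAR open/closed threshold (default 0.2).
#' @param ratioThreshold EEG alpha-prominence threshold (default 3).
#' @param expectedBlinkRate alert-baseline blink rate, blinks/min
#'   (default 15).
#' @param minCorr EOG matched-filter detection threshold (default 0.7).
#' @param tolerance EOG coincidence tolerance in seconds (default 0.05).
#' @param persistence consecutive DROWSY windows required to open a warning
#'   (default 2).
#' @param fuzzy the \linkS4class{FuzzySystem} used for fusion.
#' @return a validated config list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(channel1Source = c("EOG", "EEG"), window = 10,
                           hop = 5, earThreshold = 0.2, ratioThreshold = 3,
                           expectedBlinkRate = 15, minCorr = 0.7,
                           tolerance = 0.05, persistence = 2L,
                           fuzzy = fuzzySystem()) {
  channel1Source <- match.arg(channel1Source)
  if (!(hop > 0 && hop <= window))
    stop("require 0 < hop <= window")
  if (persistence < 1L) stop("persistence must be >= 1")
  structure(list(channel1Source = channel1Source, window = window,
                 hop = hop, earThreshold = earThreshold,
                 ratioThreshold = ratioThreshold,
                 expectedBlinkRate = expectedBlinkRate, minCorr = minCorr,
                 tolerance = tolerance, persistence = as.integer(persistence),
                 fuzzy = fuzzy),
            class = "pipelineConfig")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' The file may set any argument of \code{\link{pipelineConfig}} by name
#' (channel1Source, window, hop, earThreshold, ratioThreshold,
#' expectedBlinkRate, minCorr, tolerance, persistence), plus an optional
#' \code{fuzzy} block with input/output trapezoid breakpoints
#' (\code{inputL}, \code{inputH}, \code{outputDR}, \code{outputAL}).
#' Omitted keys keep their defaults; unknown keys are an error, so typos
#' fail loudly rather than being silently ignored.
#'
#' @param path a .yml/.yaml or .json file.
#' @return a validated config list, as \code{\link{pipelineConfig}} returns.
#' @export
readPipelineConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yml = ,
    yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("config must be a YAML or JSON file"))
  fz <- raw$fuzzy
  raw$fuzzy <- NULL
  known <- setdiff(names(formals(pipelineConfig)), "fuzzy")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  fuzzyArgs <- list()
  if (!is.null(fz)) {
    badF <- setdiff(names(fz), c("inputL", "inputH", "outputDR", "outputAL",
                                 "gridN", "decisionThreshold"))
    if (length(badF))
      stop("unknown fuzzy config keys: ", paste(badF, collapse = ", "))
    fuzzyArgs <- lapply(fz, as.numeric)
  }
  do.call(pipelineConfig,
          c(raw, list(fuzzy = do.call(fuzzySystem, fuzzyArgs))))
}

#' Run the full drowsiness detection pipeline over a session
#'
#' For every sliding window the three channel scores are computed — input 1
#' from EOG blink rate or EEG alpha prominence (per config), input 2 the
#' fraction of frames the eye-state classifier calls open, input 3 the
#' open-eye fraction of the EAR series — and fused by the Mamdani system
#' into a crisp value and DROWSY/ALERT label. No state crosses windows.
#'
#' @param session session list as produced by \code{\link{genSession}} or
#'   \code{\link{loadSession}}.
#' @param model a trained \linkS4class{EyeStateModel} for the
#'   face-recognition channel.
#' @param config a \code{\link{pipelineConfig}}.
#' @return a \linkS4class{DecisionTimeline}.
#' @export
runPipeline <- function(session, model, config = pipelineConfig()) {
  stopifnot(inherits(config, "pipelineConfig"), is(model, "EyeStateModel"))
  for (part in c("landmarks", "frameRate", "images", "imageTimes", "eeg"))
    if (is.null(session[[part]]))
      stop("session is missing the required input: ", part)
  if (config$channel1Source == "EOG" && is.null(session$eog))
    stop("session is missing the required input: eog (channel 1 source)")
  fps <- session$frameRate
  ear <- earSeriesFromLandmarks(session$landmarks, frameRate = fps)
  duration <- length(ear) / fps
  frameT <- (seq_along(earValues(ear)) - 0.5) / fps
  frLabels <- predictEyeStates(model, session$images)
  # channel-1 evidence is computed once over the whole stream, then windowed
  if (config$channel1Source == "EOG") {
    filtered <- preprocessEog(session$eog$stream)
    pulses <- detectStreamPulses(filtered, minCorr = config$minCorr)
    blinks <- detectBlinkSignature(pulses, tolerance = config$tolerance)
  }
  eegFs <- sampleRate(session$eeg)
  eegX <- eegSamples(session$eeg)
  starts <- seq(0, duration - config$window, by = config$hop)
  rows <- lapply(starts, function(t0) {
    t1 <- t0 + config$window
    if (config$channel1Source == "EOG") {
      inWin <- blinks[blinks$time_s >= t0 & blinks$time_s < t1, ,
                      drop = FALSE]
      s1 <- eogChannelScore(inWin, config$window,
                            expectedRate = config$expectedBlinkRate)
    } else {
      idx <- seq.int(floor(t0 * eegFs) + 1L, min(length(eegX),
                                                 ceiling(t1 * eegFs)))
      spec <- computePsd(EegEpoch(eegX[idx], sampleRate = eegFs))
      s1 <- eegChannelScore(spec, ratioThreshold = config$ratioThreshold)
    }
    imgSel <- session$imageTimes >= t0 & session$imageTimes < t1
    s2 <- frChannelScore(frLabels[imgSel])
    winEar <- EarSeries(earValues(ear)[frameT >= t0 & frameT < t1],
                        frameRate = fps)
    s3 <- earChannelScore(winEar, threshold = config$earThreshold)
    dec <- fuzzyDecide(config$fuzzy, c(s1, s2, s3))
    data.frame(start = t0, end = t1, score1 = s1, score2 = s2, score3 = s3,
               crisp = dec$crisp, label = dec$label)
  })
  new("DecisionTimeline", windows = do.call(rbind, rows))
}

#' Derive warning events from a decision timeline
#'
#' A warning opens when at least \code{persistence} consecutive DROWSY
#' windows have occurred (it covers the run from its first window) and
#' closes at the next ALERT window. Downstream vehicle intervention is out
#' of scope: the warning event is the system's terminal output.
#'
#' @param tl a \linkS4class{DecisionTimeline}.
#' @param persistence required consecutive DROWSY windows, >= 1 (default 2).
#' @return data.frame with columns \code{start}, \code{end} (seconds) and
#'   \code{nWindows}; zero rows when no run is long enough.
#' @export
emitWarnings <- function(tl, persistence = 2L) {
  if (persistence < 1L) stop("persistence must be >= 1")
  w <- timelineWindows(tl)
  r <- rle(w$label == "DROWSY")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= persistence
  data.frame(start = w$start[starts[keep]], end = w$end[ends[keep]],
             nWindows = r$lengths[keep])
}
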
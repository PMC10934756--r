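#' @import methods
NULL

#' EarSeries: a per-frame eye-aspect-ratio trace
#'
#' One EAR value per video frame, together with the frame rate. The EAR is
#' dimensionless and non-negative; high values correspond to open eyes, values
#' near zero to closed lids.
#'
#' @slot values numeric vector of EAR ratios, one per frame, finite and >= 0.
#' @slot frameRate frames per second, > 0.
#' @exportClass EarSeries
setClass("EarSeries",
  representation(values = "numeric", frameRate = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
        object@frameRate <= 0)
      msg <- c(msg, "frameRate must be a single positive finite number")
    if (length(object@values) && (!all(is.finite(object@values)) ||
        any(object@values < 0)))
      msg <- c(msg, "EAR values must be finite and >= 0")
    if (length(msg)) msg else TRUE
  })

#' EogStream: three synchronized electrooculography channels
#'
#' Columns EOG1/EOG2/EOG3 hold equal-length amplitude sequences (arbitrary
#' units) sampled at a common rate. EOG1/EOG2 sit lateral to the eyes
#' (horizontal movements), EOG3 above (vertical movements); a blink produces
#' the pulse-type configuration S2 on EOG1 and S1 on EOG2 and EOG3.
#'
#' @slot sampleRate sampling rate in Hz, > 0.
#' @slot channels numeric matrix, one column per channel, named EOG1..EOG3.
#' @exportClass EogStream
setClass("EogStream",
  representation(sampleRate = "numeric", channels = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
        object@sampleRate <= 0)
      msg <- c(msg, "sampleRate must be a single positive number")
    if (ncol(object@channels) != 3L ||
        !identical(colnames(object@channels), c("EOG1", "EOG2", "EOG3")))
      msg <- c(msg, "channels must have exactly the columns EOG1, EOG2, EOG3")
    if (length(object@channels) && !all(is.finite(object@channels)))
      msg <- c(msg, "all samples must be finite")
    if (length(msg)) msg else TRUE
  })

#' EegEpoch: a single-channel EEG segment
#'
#' @slot sampleRate sampling rate in Hz, > 0.
#' @slot samples amplitude sequence (microvolt scale, arbitrary units); the
#'   epoch must span at least 2 s so the 0.5 Hz delta edge is resolvable.
#' @exportClass EegEpoch
setClass("EegEpoch",
  representation(sampleRate = "numeric", samples = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
        object@sampleRate <= 0)
      msg <- c(msg, "sampleRate must be a single positive number")
    if (!all(is.finite(object@samples)))
      msg <- c(msg, "samples must be finite")
    if (length(object@samples) / object@sampleRate < 2)
      msg <- c(msg, "epoch must be at least 2 s long")
    if (length(msg)) msg else TRUE
  })

#' EegSpectrum: a one-sided power-spectral-density estimate
#'
#' @slot frequencies ascending Hz grid, from 0 (or near) up to Nyquist.
#' @slot psd power density per frequency bin, >= 0 (units amplitude^2/Hz).
#' @exportClass EegSpectrum
setClass("EegSpectrum",
  representation(frequencies = "numeric", psd = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@frequencies) != length(object@psd))
      msg <- c(msg, "frequencies and psd must have equal length")
    if (is.unsorted(object@frequencies, strictly = TRUE))
      msg <- c(msg, "frequencies must be strictly ascending")
    if (length(object@psd) && (any(!is.finite(object@psd)) ||
        any(object@psd < -1e-12)))
      msg <- c(msg, "psd must be finite and non-negative")
    if (length(msg)) msg else TRUE
  })

#' EyeImage: a grayscale eye-region raster with optional open/closed label
#'
#' After preprocessing the raster is exactly 51 x 51 with intensities in
#' [0, 1]; flattened row-major it is the 2601-element input vector of the
#' eye-state classifiers.
#'
#' @slot raster numeric matrix of intensities in [0, 1].
#' @slot label "OPEN_OR_HALF", "CLOSED", or NA when unlabeled.
#' @slot sourceSize integer(2), (rows, cols) of the raster before
#'   crop/down-sampling.
#' @exportClass EyeImage
setClass("EyeImage",
  representation(raster = "matrix", label = "character",
                 sourceSize = "integer"),
  prototype(label = NA_character_),
  validity = function(object) {
    msg <- character()
    r <- object@raster
    if (!is.numeric(r) || !length(r))
      msg <- c(msg, "raster must be a nonempty numeric matrix")
    else if (any(!is.finite(r)) || min(r) < -1e-9 || max(r) > 1 + 1e-9)
      msg <- c(msg, "intensities must be finite and within [0, 1]")
    if (length(object@label) != 1L ||
        !(is.na(object@label) ||
          object@label %in% c("OPEN_OR_HALF", "CLOSED")))
      msg <- c(msg, "label must be OPEN_OR_HALF, CLOSED or NA")
    if (length(object@sourceSize) != 2L)
      msg <- c(msg, "sourceSize must be integer(2)")
    if (length(msg)) msg else TRUE
  })

#' EyeStateModel: a trained open/closed eye-state classifier
#'
#' Either a one-hidden-layer feed-forward network (2601-10-2, variant
#' \code{MLP_1H}) or a stacked autoencoder (two pretrained code layers plus a
#' 2-way output, variant \code{STACKED_AE}). Hidden units are logistic
#' sigmoids; the output layer is a 2-way softmax so scores sum to one.
#'
#' @slot variant "MLP_1H" or "STACKED_AE".
#' @slot layers list of layers, each \code{list(W, b)}; \code{W} maps the
#'   previous layer (columns) to this layer (rows).
#' @slot trainingSeed integer seed used for weight initialization.
#' @slot classes class labels in output order.
#' @exportClass EyeStateModel
setClass("EyeStateModel",
  representation(variant = "character", layers = "list",
                 trainingSeed = "integer", classes = "character"),
  validity = function(object) {
    msg <- character()
    if (!(object@variant %in% c("MLP_1H", "STACKED_AE")))
      msg <- c(msg, "variant must be MLP_1H or STACKED_AE")
    if (!length(object@layers))
      msg <- c(msg, "model has no layers (untrained)")
    else {
      if (ncol(object@layers[[1L]]$W) != 2601L)
        msg <- c(msg, "input width must be 2601 (a flattened 51x51 raster)")
      last <- object@layers[[length(object@layers)]]
      if (nrow(last$W) != 2L)
        msg <- c(msg, "output width must be 2")
      if (!all(vapply(object@layers,
                      function(l) all(is.finite(l$W)) && all(is.finite(l$b)),
                      logical(1))))
        msg <- c(msg, "weights must be finite")
    }
    if (length(object@classes) != 2L)
      msg <- c(msg, "exactly two classes required")
    if (length(msg)) msg else TRUE
  })

#' FuzzySystem: a three-input Mamdani drowsiness fusion system
#'
#' Inputs are unit-interval channel scores (EEG-or-EOG, face recognition,
#' EAR), each with Low/High trapezoidal membership functions; the output has
#' DR (drowsy) and AL (alert) trapezoids on [0, 1]. The rule base covers all
#' eight L/H corners; AND = min, implication = clip, aggregation = max,
#' defuzzification = centroid.
#'
#' @slot inputMf list of 3 per-input lists, each with trapezoid breakpoints
#'   \code{L} and \code{H} (numeric(4), a <= b <= c <= d in [0, 1]).
#' @slot outputMf list with trapezoids \code{DR} and \code{AL}.
#' @slot rules data.frame with columns in1, in2, in3 ("L"/"H") and out
#'   ("DR"/"AL"), all 8 corners exactly once.
#' @slot gridN number of points of the output-domain discretization.
#' @slot decisionThreshold crisp values below it are labeled DROWSY.
#' @exportClass FuzzySystem
setClass("FuzzySystem",
  representation(inputMf = "list", outputMf = "list", rules = "data.frame",
                 gridN = "integer", decisionThreshold = "numeric"),
  validity = function(object) {
    msg <- character()
    okTrap <- function(p) length(p) == 4L && all(is.finite(p)) &&
      !is.unsorted(p) && p[1] >= 0 && p[4] <= 1
    if (length(object@inputMf) != 3L ||
        !all(vapply(object@inputMf,
                    function(m) okTrap(m$L) && okTrap(m$H), logical(1))))
      msg <- c(msg, "inputMf must hold L/H trapezoids for 3 inputs")
    if (!all(c("DR", "AL") %in% names(object@outputMf)) ||
        !okTrap(object@outputMf$DR) || !okTrap(object@outputMf$AL))
      msg <- c(msg, "outputMf must hold DR and AL trapezoids")
    r <- object@rules
    if (nrow(r) != 8L ||
        anyDuplicated(r[, c("in1", "in2", "in3")]) ||
        !all(unlist(r[, c("in1", "in2", "in3")]) %in% c("L", "H")) ||
        !all(r$out %in% c("DR", "AL")))
      msg <- c(msg, "rules must cover the 8 L/H corners exactly once")
    if (object@gridN < 11L)
      msg <- c(msg, "gridN too coarse for centroid defuzzification")
    if (length(msg)) msg else TRUE
  })

#' DecisionTimeline: fused drowsy/alert decisions over sliding windows
#'
#' @slot windows data.frame with columns start, end (s), score1, score2,
#'   score3, crisp, label ("DROWSY"/"ALERT"), ordered by start.
#' @exportClass DecisionTimeline
setClass("DecisionTimeline",
  representation(windows = "data.frame"),
  validity = function(object) {
    w <- object@windows
    need <- c("start", "end", "score1", "score2", "score3", "crisp", "label")
    msg <- character()
    if (!all(need %in% names(w)))
      msg <- c(msg, paste("windows needs columns:", paste(need, collapse = ", ")))
    else {
      if (nrow(w) && is.unsorted(w$start))
        msg <- c(msg, "windows must be ordered by start")
      if (nrow(w) && !all(w$label %in% c("DROWSY", "ALERT")))
        msg <- c(msg, "labels must be DROWSY or ALERT")
    }
    if (length(msg)) msg else TRUE
  })

#' SessionScenario: ground-truth description of a synthetic session
#'
#' Stands in for an instrumented drive: when blinks occur, when the driver is
#' drowsy, and per-modality signal-to-noise ratios, all under one seed.
#'
#' @slot duration session length in seconds.
#' @slot blinkTimes blink instants in seconds, within [0, duration).
#' @slot drowsyWindows numeric matrix with columns start, end (s),
#'   non-overlapping.
#' @slot snr named numeric vector of per-modality SNRs (eog, eeg, image).
#' @slot seed master integer seed.
#' @exportClass SessionScenario
setClass("SessionScenario",
  representation(duration = "numeric", blinkTimes = "numeric",
                 drowsyWindows = "matrix", snr = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@duration <= 0) msg <- c(msg, "duration must be positive")
    if (length(object@blinkTimes) &&
        (any(object@blinkTimes < 0) || any(object@blinkTimes >= object@duration)))
      msg <- c(msg, "blink times must lie within [0, duration)")
    w <- object@drowsyWindows
    if (nrow(w)) {
      if (ncol(w) != 2L || any(w[, 1] >= w[, 2]) ||
          any(w[, 1] < 0) || any(w[, 2] > object@duration))
        msg <- c(msg, "drowsy windows must be valid (start < end) within the session")
      if (nrow(w) > 1L) {
        o <- order(w[, 1])
        if (any(w[o[-nrow(w)], 2] > w[o[-1L], 1]))
          msg <- c(msg, "drowsy windows must not overlap")
      }
    }
    if (length(msg)) msg else TRUE
  })

setMethod("show", "EarSeries", function(object) {
  cat(sprintf("EarSeries: %d frames @ %g fps (%.2f s)\n",
              length(object@values), object@frameRate,
              length(object@values) / object@frameRate))
  if (length(object@values))
    cat(sprintf("  EAR range [%.3f, %.3f], mean %.3f\n",
                min(object@values), max(object@values), mean(object@values)))
})

setMethod("show", "EogStream", function(object) {
  cat(sprintf("EogStream: 3 channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(object@channels), object@sampleRate,
              nrow(object@channels) / object@sampleRate))
})

setMethod("show", "EegEpoch", function(object) {
  cat(sprintf("EegEpoch: %d samples @ %g Hz (%.2f s)\n",
              length(object@samples), object@sampleRate,
              length(object@samples) / object@sampleRate))
})

setMethod("show", "EegSpectrum", function(object) {
  cat(sprintf("EegSpectrum: %d bins, %.2f-%.2f Hz\n",
              length(object@frequencies), min(object@frequencies),
              max(object@frequencies)))
  bp <- try(bandPowers(object), silent = TRUE)
  if (!inherits(bp, "try-error"))
    cat(sprintf("  band powers: delta %.3g, theta %.3g, alpha %.3g, beta %.3g\n",
                bp["delta"], bp["theta"], bp["alpha"], bp["beta"]))
})

setMethod("show", "EyeImage", function(object) {
  cat(sprintf("EyeImage: %dx%d raster, label %s (source %dx%d)\n",
              nrow(object@raster), ncol(object@raster),
              ifelse(is.na(object@label), "<none>", object@label),
              object@sourceSize[1], object@sourceSize[2]))
})

setMethod("show", "EyeStateModel", function(object) {
  widths <- c(ncol(object@layers[[1L]]$W),
              vapply(object@layers, function(l) nrow(l$W), integer(1)))
  cat(sprintf("EyeStateModel (%s): %s, seed %d\n", object@variant,
              paste(widths, collapse = "-"), object@trainingSeed))
})

setMethod("show", "FuzzySystem", function(object) {
  cat(sprintf("FuzzySystem: 3 inputs (L/H), output DR/AL, %d rules, grid %d\n",
              nrow(object@rules), object@gridN))
})

setMethod("show", "DecisionTimeline", function(object) {
  w <- object@windows
  cat(sprintf("DecisionTimeline: %d windows, %d DROWSY / %d ALERT\n",
              nrow(w), sum(w$label == "DROWSY"), sum(w$label == "ALERT")))
})

setMethod("show", "SessionScenario", function(object) {
  cat(sprintf("SessionScenario: %.0f s, %d blinks, %d drowsy window(s), seed %d\n",
              object@duration, length(object@blinkTimes),
              nrow(object@drowsyWindows), object@seed))
})
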
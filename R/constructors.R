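#' Construct an EAR time series
#'
#' @param values numeric vector of EAR ratios, one per frame.
#' @param frameRate frames per second (default 25).
#' @return an \linkS4class{EarSeries}.
#' @examples
#' EarSeries(c(0.3, 0.3, 0.05, 0.3), frameRate = 25)
#' @export
EarSeries <- function(values, frameRate = 25) {
  new("EarSeries", values = as.numeric(values),
      frameRate = as.numeric(frameRate))
}

#' Construct a three-channel EOG stream
#'
#' @param eog1,eog2,eog3 equal-length numeric amplitude vectors.
#' @param sampleRate sampling rate in Hz (default 250).
#' @return an \linkS4class{EogStream}.
#' @export
EogStream <- function(eog1, eog2, eog3, sampleRate = 250) {
  if (length(eog1) != length(eog2) || length(eog2) != length(eog3))
    stop("all three EOG channels must have the same length")
  ch <- cbind(EOG1 = as.numeric(eog1), EOG2 = as.numeric(eog2),
              EOG3 = as.numeric(eog3))
  new("EogStream", sampleRate = as.numeric(sampleRate), channels = ch)
}

#' Construct an EEG epoch
#'
#' @param samples numeric amplitude vector (at least 2 s worth of samples).
#' @param sampleRate sampling rate in Hz (default 128).
#' @return an \linkS4class{EegEpoch}.
#' @export
EegEpoch <- function(samples, sampleRate = 128) {
  new("EegEpoch", samples = as.numeric(samples),
      sampleRate = as.numeric(sampleRate))
}

#' Construct an EEG spectrum from explicit grid and density values
#'
#' Mostly useful in tests; analysis code obtains spectra from
#' \code{\link{computePsd}}.
#'
#' @param frequencies ascending Hz grid.
#' @param psd non-negative power densities, same length.
#' @return an \linkS4class{EegSpectrum}.
#' @export
EegSpectrum <- function(frequencies, psd) {
  new("EegSpectrum", frequencies = as.numeric(frequencies),
      psd = as.numeric(psd))
}

#' Construct an eye image
#'
#' @param raster numeric intensity matrix in [0, 1].
#' @param label optional "OPEN_OR_HALF" or "CLOSED".
#' @param sourceSize original (rows, cols) before preprocessing; defaults to
#'   the raster's own size.
#' @return an \linkS4class{EyeImage}.
#' @export
EyeImage <- function(raster, label = NA_character_, sourceSize = dim(raster)) {
  new("EyeImage", raster = raster, label = as.character(label),
      sourceSize = as.integer(sourceSize))
}

#' Construct a session scenario for the synthetic generators
#'
#' @param duration session length in seconds.
#' @param blinkTimes blink instants (s).
#' @param drowsyWindows two-column matrix (start, end) in seconds, or NULL.
#' @param snr named per-modality signal-to-noise ratios.
#' @param seed master integer seed.
#' @return a \linkS4class{SessionScenario}.
#' @export
SessionScenario <- function(duration, blinkTimes = numeric(),
                            drowsyWindows = NULL,
                            snr = c(eog = 10, eeg = 5, image = 20),
                            seed = 1L) {
  if (is.null(drowsyWindows))
    drowsyWindows <- matrix(numeric(), ncol = 2)
  drowsyWindows <- matrix(as.numeric(drowsyWindows), ncol = 2,
                          dimnames = list(NULL, c("start", "end")))
  new("SessionScenario", duration = as.numeric(duration),
      blinkTimes = sort(as.numeric(blinkTimes)),
      drowsyWindows = drowsyWindows, snr = snr, seed = as.integer(seed))
}

#' @name accessors
#' @title Accessors for DrowsyFusion data classes
#' @param x the object.
#' @return the corresponding slot value.
NULL

#' @rdname accessors
#' @export
setMethod("frameRate", "EarSeries", function(x) x@frameRate)

#' @rdname accessors
#' @export
setMethod("earValues", "EarSeries", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("sampleRate", "EogStream", function(x) x@sampleRate)

#' @rdname accessors
#' @export
setMethod("sampleRate", "EegEpoch", function(x) x@sampleRate)

#' @rdname accessors
#' @export
setMethod("channelMatrix", "EogStream", function(x) x@channels)

#' @rdname accessors
#' @export
setMethod("eegSamples", "EegEpoch", function(x) x@samples)

#' @rdname accessors
#' @export
setMethod("frequencies", "EegSpectrum", function(x) x@frequencies)

#' @rdname accessors
#' @export
setMethod("psdValues", "EegSpectrum", function(x) x@psd)

#' @rdname accessors
#' @export
setMethod("imageRaster", "EyeImage", function(x) x@raster)

#' @rdname accessors
#' @export
setMethod("imageLabel", "EyeImage", function(x) x@label)

#' @rdname accessors
#' @export
setMethod("timelineWindows", "DecisionTimeline", function(x) x@windows)

#' Length of an EarSeries is its number of frames
#' @param x an \linkS4class{EarSeries}.
#' @export
setMethod("length", "EarSeries", function(x) length(x@values))
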
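#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname accessors
#' @export
setGeneric("earValues", function(x) standardGeneric("earValues"))

#' @rdname accessors
#' @export
setGeneric("channelMatrix", function(x) standardGeneric("channelMatrix"))

#' @rdname accessors
#' @export
setGeneric("eegSamples", function(x) standardGeneric("eegSamples"))

#' @rdname accessors
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' @rdname accessors
#' @export
setGeneric("psdValues", function(x) standardGeneric("psdValues"))

#' Band powers of an EEG spectrum
#'
#' Integrates the power spectral density over the four canonical EEG rhythm
#' bands: delta 0.5-4 Hz, theta 4-7 Hz, alpha 8-12 Hz, beta 13-30 Hz.
#'
#' @param x an \linkS4class{EegSpectrum}.
#' @return named numeric vector with elements delta, theta, alpha, beta.
#' @export
setGeneric("bandPowers", function(x) standardGeneric("bandPowers"))

#' @rdname accessors
#' @export
setGeneric("imageRaster", function(x) standardGeneric("imageRaster"))

#' @rdname accessors
#' @export
setGeneric("imageLabel", function(x) standardGeneric("imageLabel"))

#' @rdname accessors
#' @export
setGeneric("timelineWindows", function(x) standardGeneric("timelineWindows"))
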
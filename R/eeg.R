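# EEG spectral analysis: Welch PSD, rhythm-band powers, and the alpha-peak
# drowsiness criterion. Drowsiness onset raises alpha (8-12 Hz) activity, so
# a prominent spectral peak in the 10-12 Hz domain marks a drowsy epoch,
# while alert wakefulness is dominated by beta (13-30 Hz).

#' Welch power spectral density of an EEG epoch
#'
#' Averaged modified periodogram: the mean-removed epoch is cut into
#' Hann-windowed segments with the given overlap, each segment's one-sided
#' periodogram is computed, and the periodograms are averaged. The density
#' is normalized so that its integral over frequency matches the time-domain
#' variance (Parseval, up to windowing tolerance).
#'
#' @param ep an \linkS4class{EegEpoch}.
#' @param segmentLen segment length in seconds (default 1, giving 1 Hz
#'   resolution).
#' @param overlap fractional segment overlap in [0, 1) (default 0.5).
#' @return an \linkS4class{EegSpectrum} on the grid 0..Nyquist with spacing
#'   1/segmentLen Hz.
#' @export
computePsd <- function(ep, segmentLen = 1, overlap = 0.5) {
  stopifnot(is(ep, "EegEpoch"))
  fs <- sampleRate(ep)
  x <- eegSamples(ep)
  nseg <- round(segmentLen * fs)
  if (nseg > length(x)) stop("segment longer than the epoch")
  if (!(overlap >= 0 && overlap < 1)) stop("overlap must be in [0, 1)")
  x <- x - mean(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  nfreq <- nseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * w
    spec <- abs(stats::fft(seg))^2 / (fs * sum(w^2))
    half <- spec[seq_len(nfreq)]
    half[2:(nfreq - if (nseg %% 2L == 0L) 1L else 0L)] <-
      2 * half[2:(nfreq - if (nseg %% 2L == 0L) 1L else 0L)]
    acc <- acc + half
  }
  EegSpectrum(frequencies = (seq_len(nfreq) - 1L) * fs / nseg,
              psd = acc / length(starts))
}

bandEdges <- list(delta = c(0.5, 4), theta = c(4, 7),
                  alpha = c(8, 12), beta = c(13, 30))

# Integrated PSD over [lo, hi): trapezoid-free bin sum, psd * df per bin
# whose center falls in the band. hi inclusive for alpha/beta per the stated
# band definitions (8-12, 13-30).
integrateBand <- function(freqs, psd, lo, hi, hiInclusive) {
  df <- stats::median(diff(freqs))
  sel <- freqs >= lo & (if (hiInclusive) freqs <= hi else freqs < hi)
  sum(psd[sel]) * df
}

#' @describeIn bandPowers integrates the PSD over delta (0.5-4 Hz), theta
#'   (4-7 Hz), alpha (8-12 Hz) and beta (13-30 Hz). The (7, 8) Hz gap between
#'   theta and alpha is left unassigned, exactly as the band definitions
#'   state. Errors if the grid does not reach 30 Hz.
#' @export
setMethod("bandPowers", "EegSpectrum", function(x) {
  freqs <- frequencies(x)
  if (max(freqs) < 30)
    stop("spectrum must cover at least 30 Hz to resolve the beta band")
  p <- psdValues(x)
  c(delta = integrateBand(freqs, p, 0.5, 4, FALSE),
    theta = integrateBand(freqs, p, 4, 7, FALSE),
    alpha = integrateBand(freqs, p, 8, 12, TRUE),
    beta = integrateBand(freqs, p, 13, 30, TRUE))
})

#' Alpha peak in the 10-12 Hz domain
#'
#' Locates the PSD maximum restricted to 10-12 Hz and reports its prominence
#' as the ratio of the peak density to the median density over 0.5-30 Hz
#' excluding the alpha band (8-12 Hz). A prominence near 1 means no peak
#' stands out of the background; a drowsy, alpha-dominant epoch gives a
#' ratio far above 1.
#'
#' @param spec an \linkS4class{EegSpectrum} whose grid covers 10-12 Hz.
#' @return list with \code{freq} (Hz), \code{amplitude} (density at the
#'   peak) and \code{prominenceRatio}.
#' @export
alphaPeak <- function(spec) {
  stopifnot(is(spec, "EegSpectrum"))
  freqs <- frequencies(spec)
  p <- psdValues(spec)
  inDomain <- which(freqs >= 10 & freqs <= 12)
  if (!length(inDomain))
    stop("spectrum grid has no bin inside the 10-12 Hz search domain")
  i <- inDomain[which.max(p[inDomain])]
  bg <- freqs >= 0.5 & freqs <= 30 & !(freqs >= 8 & freqs <= 12)
  if (!any(bg)) stop("spectrum too narrow for a background estimate")
  med <- stats::median(p[bg])
  list(freq = freqs[i], amplitude = p[i],
       prominenceRatio = if (med > 0) p[i] / med
                         else if (p[i] > 0) Inf else 1)
}

#' Classify an EEG epoch spectrum as drowsy or alert
#'
#' DROWSY when the 10-12 Hz alpha peak's prominence ratio reaches
#' \code{ratioThreshold}; ALERT otherwise.
#'
#' @inheritParams alphaPeak
#' @param ratioThreshold prominence ratio at or above which the epoch is
#'   drowsy (default 3).
#' @return "DROWSY" or "ALERT".
#' @export
classifyEpoch <- function(spec, ratioThreshold = 3) {
  pk <- alphaPeak(spec)
  if (pk$prominenceRatio >= ratioThreshold) "DROWSY" else "ALERT"
}

#' EEG channel score for fuzzy fusion
#'
#' Maps the alpha prominence ratio linearly onto [0, 1] so that the score is
#' 0.5 exactly at the classification threshold, approaches 1 for a flat
#' (alert) spectrum and 0 for a strongly alpha-dominant one:
#' score = clip(1 - ratio / (2 threshold)).
#'
#' @inheritParams classifyEpoch
#' @return a score in [0, 1] (high = alert evidence).
#' @export
eegChannelScore <- function(spec, ratioThreshold = 3) {
  pk <- alphaPeak(spec)
  clip01(1 - pk$prominenceRatio / (2 * ratioThreshold))
}
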
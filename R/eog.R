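# EOG pulse detection and blink-signature identification.
#
# The three periocular channels each show one of two pulse waveform classes:
# S1, a biphasic pulse (positive then negative lobe), and S2, a monophasic
# hump. A blink produces the channel configuration EOG1 = S2, EOG2 = S1,
# EOG3 = S1; no other eye movement produces that triple, so coincident
# pulses of exactly those kinds identify a blink.

#' S1 and S2 pulse templates
#'
#' Parametric stand-ins for the two recorded pulse classes: S1 is a
#' derivative-of-Gaussian (biphasic, positive lobe first), S2 a Gaussian
#' hump (monophasic). Both are unit-peak and span 6 standard deviations.
#'
#' @param sampleRate sampling rate in Hz.
#' @param width nominal pulse width in seconds (default 0.15); the Gaussian
#'   sigma is width/3 so the template support is ~2 widths.
#' @return list with numeric templates \code{S1} and \code{S2}.
#' @export
eogTemplates <- function(sampleRate = 250, width = 0.15) {
  sigma <- width / 3
  t <- seq(-3 * sigma, 3 * sigma, by = 1 / sampleRate)
  s2 <- exp(-t^2 / (2 * sigma^2))
  s1 <- -t * exp(-t^2 / (2 * sigma^2))
  s1 <- s1 / max(abs(s1))
  list(S1 = s1, S2 = s2)
}

#' Detrend and band-pass filter an EOG stream
#'
#' Removes the per-channel mean and linear trend, then applies a zero-phase
#' 4th-order Butterworth band-pass. Length and sampling rate are preserved.
#'
#' @param raw an \linkS4class{EogStream}.
#' @param band numeric(2) pass band in Hz, strictly inside (0, Nyquist);
#'   default \code{c(0.5, 20)}, wide enough to keep blink pulses intact.
#' @return the filtered \linkS4class{EogStream}.
#' @export
preprocessEog <- function(raw, band = c(0.5, 20)) {
  stopifnot(is(raw, "EogStream"))
  fs <- sampleRate(raw)
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= fs / 2)
    stop("band must lie strictly inside (0, Nyquist)")
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  ch <- apply(channelMatrix(raw), 2L, function(x) {
    n <- length(x)
    x <- stats::residuals(stats::lm.fit(cbind(1, seq_len(n)), x))
    as.numeric(signal::filtfilt(bf, x))
  })
  colnames(ch) <- c("EOG1", "EOG2", "EOG3")
  new("EogStream", sampleRate = fs, channels = ch)
}

# Normalized cross-correlation of x against a template at every lag where
# the template fits entirely; returns values in [-1, 1].
normXCorr <- function(x, template) {
  m <- length(template)
  n <- length(x) - m + 1L
  if (n < 1L) stop("template longer than channel")
  tpl <- template - mean(template)
  tplNorm <- sqrt(sum(tpl^2))
  # running sums via convolution with a box for local mean/energy
  num <- as.numeric(stats::filter(x, rev(tpl), sides = 1))[m:length(x)]
  cs <- cumsum(c(0, x)); cs2 <- cumsum(c(0, x^2))
  localSum <- cs[(m + 1):(length(x) + 1)] - cs[1:n]
  localSum2 <- cs2[(m + 1):(length(x) + 1)] - cs2[1:n]
  localVar <- pmax(localSum2 - localSum^2 / m, 0)
  denom <- sqrt(localVar) * tplNorm
  r <- ifelse(denom > 0, num / denom, 0)
  pmin(1, pmax(-1, r))
}

#' Detect S1/S2 pulses on one EOG channel by matched filtering
#'
#' Slides both templates over the channel with normalized cross-correlation;
#' local correlation maxima above \code{minCorr} are pulse candidates,
#' provided the local signal excursion also clears an amplitude gate of
#' \code{minAmp} robust noise standard deviations (the correlation itself is
#' scale-invariant, so shape alone cannot separate a pulse from a smooth
#' noise wiggle). Within one template length the best-scoring candidate
#' wins, so detections on a channel never overlap, and each detection
#' carries the kind of the best-matching template.
#'
#' @param x numeric amplitude vector (one channel).
#' @param sampleRate sampling rate in Hz.
#' @param templates list with elements \code{S1} and \code{S2} (see
#'   \code{\link{eogTemplates}}).
#' @param minCorr detection threshold on the correlation, in (0, 1];
#'   default 0.7.
#' @param minAmp amplitude gate in multiples of the channel's MAD-based
#'   noise standard deviation (default 3.5; 0 disables the gate).
#' @return data.frame with columns \code{time} (s, pulse center),
#'   \code{kind} ("S1"/"S2"), \code{score}.
#' @export
detectPulses <- function(x, sampleRate, templates = eogTemplates(sampleRate),
                         minCorr = 0.7, minAmp = 3.5) {
  if (!all(c("S1", "S2") %in% names(templates)) ||
      !length(templates$S1) || !length(templates$S2))
    stop("templates must provide nonempty S1 and S2 waveforms")
  if (!(minCorr > 0 && minCorr <= 1)) stop("minCorr must be in (0, 1]")
  noiseSd <- stats::mad(x, center = stats::median(x))
  cand <- do.call(rbind, lapply(c("S1", "S2"), function(kind) {
    tpl <- templates[[kind]]
    r <- normXCorr(x, tpl)
    n <- length(r)
    if (n < 3L) return(NULL)
    isMax <- r >= minCorr &
      r >= c(-Inf, r[-n]) & r >= c(r[-1L], -Inf)
    idx <- which(isMax)
    if (length(idx) && minAmp > 0) {
      m <- length(tpl)
      peak <- vapply(idx, function(i) {
        win <- x[i:(i + m - 1L)]
        max(abs(win - stats::median(win)))
      }, numeric(1))
      idx <- idx[peak >= minAmp * noiseSd]
    }
    if (!length(idx)) return(NULL)
    data.frame(start = idx, kind = kind, score = r[idx],
               center = idx - 1 + (length(tpl) - 1) / 2)
  }))
  if (is.null(cand) || !nrow(cand)) {
    return(data.frame(time = numeric(), kind = character(),
                      score = numeric()))
  }
  # non-maximum suppression across kinds: best score wins, suppressing any
  # candidate whose center lies within one template length
  span <- max(length(templates$S1), length(templates$S2))
  cand <- cand[order(-cand$score), ]
  keep <- logical(0)
  centers <- numeric(0)
  sel <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!length(centers) || all(abs(cand$center[i] - centers) >= span)) {
      sel <- c(sel, i)
      centers <- c(centers, cand$center[i])
    }
  }
  out <- cand[sel, ]
  out <- out[order(out$center), ]
  data.frame(time = out$center / sampleRate, kind = out$kind,
             score = out$score)
}

#' Detect pulses on all three channels of a stream
#'
#' @param stream an \linkS4class{EogStream}, ideally already passed through
#'   \code{\link{preprocessEog}}.
#' @inheritParams detectPulses
#' @return named list (EOG1, EOG2, EOG3) of pulse data.frames.
#' @export
detectStreamPulses <- function(stream, templates = NULL, minCorr = 0.7,
                               minAmp = 3.5) {
  stopifnot(is(stream, "EogStream"))
  fs <- sampleRate(stream)
  if (is.null(templates)) templates <- eogTemplates(fs)
  ch <- channelMatrix(stream)
  stats::setNames(lapply(seq_len(3L), function(i)
    detectPulses(ch[, i], fs, templates, minCorr, minAmp)),
    colnames(ch))
}

#' Identify blinks from per-channel pulses by the blink signature
#'
#' A blink requires one pulse of the right kind on every channel — S2 on
#' EOG1, S1 on EOG2, S1 on EOG3 — all within \code{tolerance} seconds of
#' each other. Matching is greedy earliest-first: scanning candidate triples
#' in time order, each pulse is consumed by at most one blink. The event
#' time is the mean of the three pulse times.
#'
#' @param pulses named list of pulse data.frames (EOG1, EOG2, EOG3), as
#'   returned by \code{\link{detectStreamPulses}}.
#' @param tolerance coincidence tolerance in seconds (default 0.05).
#' @param signature required pulse kind per channel; the default is the
#'   blink configuration.
#' @return data.frame of blink events (\code{time_s}, \code{duration_s},
#'   \code{source} = "EOG"); zero rows if no triple matches.
#' @export
detectBlinkSignature <- function(pulses, tolerance = 0.05,
                                 signature = c(EOG1 = "S2", EOG2 = "S1",
                                               EOG3 = "S1")) {
  if (!is.finite(tolerance) || tolerance <= 0)
    stop("tolerance must be positive")
  cand <- lapply(names(signature), function(chn) {
    p <- pulses[[chn]]
    if (is.null(p) || !nrow(p)) numeric()
    else sort(p$time[p$kind == signature[[chn]]])
  })
  names(cand) <- names(signature)
  used <- lapply(cand, function(t) rep(FALSE, length(t)))
  events <- numeric()
  # anchor on EOG1 candidates in time order; earliest feasible partners win
  for (i in seq_along(cand$EOG1)) {
    t1 <- cand$EOG1[i]
    j <- which(!used$EOG2 & abs(cand$EOG2 - t1) <= tolerance)
    k <- which(!used$EOG3 & abs(cand$EOG3 - t1) <= tolerance)
    found <- FALSE
    for (jj in j) {
      for (kk in k) {
        if (abs(cand$EOG2[jj] - cand$EOG3[kk]) <= tolerance) {
          events <- c(events, mean(c(t1, cand$EOG2[jj], cand$EOG3[kk])))
          used$EOG2[jj] <- TRUE
          used$EOG3[kk] <- TRUE
          found <- TRUE
          break
        }
      }
      if (found) break
    }
  }
  data.frame(time_s = events,
             duration_s = rep(2 * tolerance, length(events)),
             source = rep("EOG", length(events)))
}

#' EOG channel score for fuzzy fusion
#'
#' Maps the observed blink rate to [0, 1] by its departure from an
#' alert-baseline rate: the score is 1 at the expected rate and falls off
#' linearly at slope 1/expectedRate on both sides (absent blinking — a
#' drowsiness sign — reaches 0, as does blinking at twice the baseline),
#' clipped to [0, 1].
#'
#' @param events blink-event data.frame (column \code{time_s}).
#' @param window window length in seconds.
#' @param expectedRate alert-baseline blink rate in blinks/min (default 15,
#'   a typical relaxed adult rate).
#' @return a score in [0, 1].
#' @export
eogChannelScore <- function(events, window, expectedRate = 15) {
  if (!is.finite(window) || window <= 0) stop("window must be positive")
  if (!is.finite(expectedRate) || expectedRate <= 0)
    stop("expectedRate must be positive")
  rate <- 60 * nrow(events) / window
  clip01(1 - abs(rate - expectedRate) / expectedRate)
}
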
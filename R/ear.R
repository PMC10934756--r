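#' Euclidean distance between two 2-D pixel points
#'
#' @param a,b numeric length-2 vectors (x, y) in pixels.
#' @return distance in pixels.
#' @examples
#' euclideanDistance(c(0, 0), c(3, 4))  # 5
#' @export
euclideanDistance <- function(a, b) {
  if (length(a) != 2L || length(b) != 2L)
    stop("points must be length-2 (x, y) vectors")
  stopifnotFinite(c(a, b), "point coordinates")
  sqrt(sum((a - b)^2))
}

#' Assemble a 6-point eye landmark set
#'
#' The six points trace the eye contour counter-clockwise starting from the
#' outer corner: p1 outer corner, p2 and p3 on the upper lid, p4 inner
#' corner, p5 and p6 on the lower lid (image coordinates, y increasing
#' downward). The horizontal extent p1-p4 must be nonzero.
#'
#' @param p1,p2,p3,p4,p5,p6 numeric length-2 (x, y) pixel coordinates.
#' @return a 6 x 2 numeric matrix with rows p1..p6 and columns x, y.
#' @export
eyeLandmarks <- function(p1, p2, p3, p4, p5, p6) {
  lm <- rbind(p1 = p1, p2 = p2, p3 = p3, p4 = p4, p5 = p5, p6 = p6)
  colnames(lm) <- c("x", "y")
  stopifnotFinite(lm, "landmark coordinates")
  if (all(lm["p1", ] == lm["p4", ]))
    stop("degenerate eye: p1 and p4 coincide (zero horizontal extent)")
  lm
}

#' Eye aspect ratio from six landmarks
#'
#' EAR = (||p2 - p6|| + ||p3 - p5||) / (2 ||p1 - p4||): the two vertical
#' lid separations summed, normalized by twice the horizontal eye width.
#' High values mean the eye is open; a fully closed lid gives 0. Being a
#' ratio of Euclidean distances, the EAR is invariant under translation,
#' rotation, and uniform scaling of the landmark set.
#'
#' @param lm a 6 x 2 landmark matrix from \code{\link{eyeLandmarks}} (rows
#'   p1..p6, columns x, y).
#' @return the EAR, a dimensionless non-negative ratio.
#' @examples
#' lm <- eyeLandmarks(c(0, 0), c(1, 1), c(3, 1), c(4, 0), c(3, -1), c(1, -1))
#' computeEAR(lm)  # 0.5
#' @export
computeEAR <- function(lm) {
  if (!is.matrix(lm) || nrow(lm) != 6L || ncol(lm) != 2L)
    stop("landmarks must be a 6 x 2 matrix (rows p1..p6)")
  stopifnotFinite(lm, "landmark coordinates")
  width <- euclideanDistance(lm[1L, ], lm[4L, ])
  if (width == 0)
    stop("degenerate eye: p1 and p4 coincide (zero horizontal extent)")
  (euclideanDistance(lm[2L, ], lm[6L, ]) +
     euclideanDistance(lm[3L, ], lm[5L, ])) / (2 * width)
}

#' Segment closed-eye intervals from an EAR series
#'
#' A simple threshold rule: frames with EAR strictly below \code{threshold}
#' are closed (equality counts as open). Maximal runs of consecutive closed
#' frames are returned as half-open, 0-based frame intervals.
#'
#' @param s an \linkS4class{EarSeries}.
#' @param threshold EAR threshold, > 0; default 0.2, the usual convention in
#'   the EAR literature.
#' @return data.frame with columns \code{start} (inclusive) and \code{end}
#'   (exclusive), ascending and non-overlapping; zero rows when no frame is
#'   closed.
#' @examples
#' segmentEarSeries(EarSeries(c(0.3, 0.3, 0.05, 0.05, 0.3)), threshold = 0.15)
#' @export
segmentEarSeries <- function(s, threshold = 0.2) {
  stopifnot(is(s, "EarSeries"))
  if (!length(earValues(s))) stop("EAR series is empty")
  if (!is.finite(threshold) || threshold <= 0)
    stop("threshold must be positive")
  closed <- earValues(s) < threshold
  r <- rle(closed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Extract blink events from an EAR series
#'
#' Closed intervals whose duration falls within [minDur, maxDur] are counted
#' as blinks; longer closures are treated as prolonged eye closure (a
#' drowsiness sign in its own right) and are deliberately not reported as
#' blinks. The event time is the interval midpoint.
#'
#' @param s an \linkS4class{EarSeries}.
#' @param threshold EAR threshold (see \code{\link{segmentEarSeries}}).
#' @param minDur,maxDur blink duration gate in seconds (defaults 0.04 and
#'   0.5).
#' @return data.frame of blink events with columns \code{time_s},
#'   \code{duration_s}, \code{source} (= "EAR").
#' @export
extractBlinkEvents <- function(s, threshold = 0.2, minDur = 0.04,
                               maxDur = 0.5) {
  stopifnot(is(s, "EarSeries"))
  if (!(minDur > 0 && minDur < maxDur))
    stop("require 0 < minDur < maxDur")
  iv <- segmentEarSeries(s, threshold)
  fps <- frameRate(s)
  dur <- (iv$end - iv$start) / fps
  keep <- dur >= minDur & dur <= maxDur
  data.frame(time_s = (iv$start[keep] + iv$end[keep]) / 2 / fps,
             duration_s = dur[keep],
             source = rep("EAR", sum(keep)))
}

#' Blink frequency and interval statistics
#'
#' @param events blink-event data.frame (columns \code{time_s}, ...), e.g.
#'   from \code{\link{extractBlinkEvents}} or
#'   \code{\link{detectBlinkSignature}}.
#' @param window observation window length in seconds.
#' @return list with \code{rate} (blinks/min), \code{meanInterval} and
#'   \code{intervalSd} (s; \code{NA} when fewer than 2 events), and
#'   \code{count}.
#' @export
blinkStatistics <- function(events, window) {
  if (!is.finite(window) || window <= 0)
    stop("window must be a positive duration in seconds")
  n <- nrow(events)
  gaps <- if (n >= 2L) diff(sort(events$time_s)) else numeric()
  list(rate = 60 * n / window,
       meanInterval = if (length(gaps)) mean(gaps) else NA_real_,
       intervalSd = if (length(gaps) >= 2L) stats::sd(gaps) else NA_real_,
       count = n)
}

#' EAR channel score for fuzzy fusion
#'
#' The fraction of frames at or above the threshold, i.e. the open-eye
#' fraction of the window: 1 is fully open (alert evidence), 0 fully closed.
#' Complements the closed-frame fraction exactly to 1.
#'
#' @inheritParams segmentEarSeries
#' @return a score in [0, 1].
#' @export
earChannelScore <- function(s, threshold = 0.2) {
  stopifnot(is(s, "EarSeries"))
  if (!length(earValues(s))) stop("EAR series is empty")
  mean(earValues(s) >= threshold)
}

#' Compute an EAR series from per-frame landmarks
#'
#' @param frames list of 6 x 2 landmark matrices (one per frame), e.g. from
#'   \code{\link{genLandmarks}} or \code{\link{readLandmarksCsv}}.
#' @param frameRate frames per second.
#' @return an \linkS4class{EarSeries}.
#' @export
earSeriesFromLandmarks <- function(frames, frameRate = 25) {
  EarSeries(vapply(frames, computeEAR, numeric(1)), frameRate = frameRate)
}
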